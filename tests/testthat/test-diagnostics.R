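test_that("ROC thresholds are midpoints with sentinels", {
  roc <- build_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(roc$threshold, c(-Inf, 1.5, 2.5, 3.5, Inf))
  at25 <- roc[roc$threshold == 2.5, ]
  expect_equal(at25$sensitivity, 1)
  expect_equal(at25$specificity, 1)
  # endpoints reach the chance corners
  expect_equal(roc$sensitivity[1], 1)
  expect_equal(roc$specificity[1], 0)
  expect_equal(roc$sensitivity[nrow(roc)], 0)
  expect_equal(roc$specificity[nrow(roc)], 1)

  expect_error(build_roc(c(1, 2), c(1, 1)), "both classes")
  tied <- build_roc(rep(2, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(nrow(tied), 2) # only the sentinel corner points remain
})

test_that("ROC curves are monotone for random inputs", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n, 0, 12), sample(0:1, 1))
    roc <- build_roc(scores, labels)
    expect_true(all(diff(roc$sensitivity) <= 1e-12))
    expect_true(all(diff(1 - roc$specificity) <= 1e-12))
  }
})

test_that("trapezoidal AUC equals the pair-counting oracle", {
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(3, 8), c(0, 1, 0, 1, 0, 1, 0, 1)), 0.5)

  set.seed(32)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n, 0, 10), 1) # heavy ties on purpose
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC confidence interval agrees with the DeLong reference", {
  skip_if_not_installed("pROC")
  set.seed(33)
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.6, 0.4))
  scores <- round(stats::rnorm(60, mean = labels), 1)
  ours <- roc_auc_ci(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                      method = "delong")
  expect_equal(unname(ours["auc"]), as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(unname(ours["lower"]), as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(unname(ours["upper"]), as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("Youden cutoff matches exhaustive search, smallest on ties", {
  roc <- build_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  yc <- youden_cutoff(roc)
  expect_equal(yc$cutoff, 2.5)
  expect_equal(yc$youden_j, 1)

  # one-decimal scores straddling 2.1/2.2: optimum lands on the midpoint
  yc2 <- youden_cutoff(build_roc(c(1.0, 1.5, 2.1, 2.2, 3.0, 4.0),
                                 c(0, 0, 0, 1, 1, 1)))
  expect_equal(yc2$cutoff, 2.15)

  # chance line: J = 0 everywhere, tie broken to the lowest candidate
  suppressMessages(
    yc3 <- youden_cutoff(build_roc(rep(2, 4), c(0, 1, 0, 1)))
  )
  expect_equal(yc3$youden_j, 0)
  expect_equal(yc3$cutoff, -Inf)

  set.seed(34)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n, 0, 6), 1)
    yc <- suppressMessages(youden_cutoff(build_roc(scores, labels)))
    oracle <- oracle_youden(scores, labels)
    expect_equal(yc$cutoff, oracle$cutoff)
    expect_equal(yc$youden_j, oracle$j, tolerance = 1e-12)
  }
})

test_that("confusion counts and metrics are exact", {
  cm <- confusion_at(c(1, 2, 3, 4), c(0, 0, 1, 1), 2.5)
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  low <- confusion_at(c(1, 2, 3, 4), c(0, 0, 1, 1), 0)
  expect_equal(low$tp, 2L)
  expect_equal(low$tn, 0L)
  high <- confusion_at(c(1, 2, 3, 4), c(0, 0, 1, 1), 99)
  expect_equal(high$tp, 0L)
  expect_equal(high$tn, 2L)

  m <- cm_metrics(new_cm(16, 3, 44, 1))
  expect_equal(unname(m["ppv"]), 0.842)
  expect_equal(unname(m["npv"]), 0.978)
  m2 <- cm_metrics(new_cm(17, 3, 44, 0))
  expect_equal(unname(m2[c("sensitivity", "ppv", "npv")]), c(1, 0.85, 1))

  expect_warning(m3 <- cm_metrics(new_cm(0, 0, 1, 1)), "PPV undefined")
  expect_true(is.na(m3["ppv"]))
  expect_equal(unname(m3["specificity"]), 1)
  expect_equal(unname(m3["npv"]), 0.5)
})

test_that("confusion matrices reconstruct from reported rates", {
  cm <- counts_from_rates(0.765, 0.638, 17, 47)
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = 13L, fp = 17L, tn = 30L, fn = 4L))
  cm2 <- counts_from_rates(1, 0.936, 17, 47)
  expect_equal(unclass(cm2)[c("tp", "fp", "tn", "fn")],
               list(tp = 17L, fp = 3L, tn = 44L, fn = 0L))
  cm3 <- counts_from_rates(0.5, 0.5, 2, 2)
  expect_equal(unclass(cm3)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_silent(counts_from_rates(0.3, 0.9, 10, 10)) # 3/10 and 9/10 exactly
  expect_warning(counts_from_rates(0.32, 0.9, 10, 10), "inconsistent")
})

test_that("metrics and counts_from_rates round-trip", {
  set.seed(35)
  for (i in 1:100) {
    n_pos <- sample(2:60, 1)
    n_neg <- sample(2:60, 1)
    tp <- sample(0:n_pos, 1)
    tn <- sample(0:n_neg, 1)
    sens <- round(tp / n_pos, 3)
    spec <- round(tn / n_neg, 3)
    cm <- suppressWarnings(counts_from_rates(sens, spec, n_pos, n_neg))
    # reconstruction inverts 3-decimal rounding whenever it is invertible
    if (abs(sens * n_pos - round(sens * n_pos)) < 0.49 &&
        abs(spec * n_neg - round(spec * n_neg)) < 0.49) {
      m <- suppressWarnings(cm_metrics(cm, digits = 3))
      expect_equal(unname(m["sensitivity"]), sens)
      expect_equal(unname(m["specificity"]), spec)
    }
  }
})

test_that("diagnose summarizes one score end to end", {
  scores <- c(1.1, 1.8, 2.1, 2.2, 3.4, 4.0)
  labels <- c(0, 0, 0, 1, 1, 1)
  d <- diagnose(scores, labels)
  expect_equal(d$auc, 1)
  expect_equal(d$cutoff, 2.15)
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  expect_equal(d$youden_j, d$sensitivity + d$specificity - 1)
  expect_equal(d$n_pos, 3L)
  expect_equal(d$n_neg, 3L)
})
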