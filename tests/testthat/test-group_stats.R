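test_that("chi-square reproduces published group comparisons", {
  # sex by bone status among the disease group
  res <- chi_square_independence(rbind(c(10, 17, 13), c(14, 6, 4)))
  expect_equal(res$statistic, 7.1384, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(round(res$p_value, 3), 0.028)

  flat <- chi_square_independence(matrix(5, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  hand <- chi_square_independence(rbind(c(3, 1), c(1, 3)))
  oracle <- oracle_chisq(rbind(c(3, 1), c(1, 3)))
  expect_equal(hand$statistic, oracle$statistic) # = 2 by hand
  expect_equal(hand$statistic, 2)
  expect_equal(hand$p_value, oracle$p)

  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "zero")
  expect_error(chi_square_independence(rbind(c(1.5, 1), c(1, 2))),
               "integers")
})

test_that("chi-square matches the direct formula on random tables", {
  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(sample(1:20, 6, replace = TRUE), 2, 3)
    res <- chi_square_independence(tab)
    oracle <- oracle_chisq(tab)
    expect_equal(res$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(rbind(c(0, 5), c(5, 0)))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(2, 2), c(2, 2)))$p_value, 1)
  expect_error(fisher_exact(matrix(1, 2, 3)), "2x2")

  set.seed(42)
  for (i in 1:25) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U: exact small-sample p and the U identity", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$statistic %in% c(0, 9)) # orientation: U for x
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)

  same <- mann_whitney(c(3, 1, 2), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)

  set.seed(43)
  for (i in 1:20) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    x <- round(stats::rnorm(nx, 0, 3), 3)
    y <- round(stats::rnorm(ny, 1, 3), 3)
    ux <- mann_whitney(x, y)$statistic
    uy <- mann_whitney(y, x)$statistic
    expect_equal(ux + uy, nx * ny)
    if (length(unique(c(x, y))) == nx + ny) {
      expect_equal(mann_whitney(x, y)$p_value, oracle_mw_exact_p(x, y),
                   tolerance = 1e-12)
    }
  }

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("summary-statistic ANOVA reproduces the published age test", {
  res <- anova_oneway(summaries = data.frame(
    mean = c(44.38, 49.48, 54.35),
    sd = c(10.38, 12.47, 9.76),
    n = c(24, 23, 17)
  ))
  expect_equal(round(res$p_value, 3), 0.021)
  expect_equal(res$df, "2,61")
})

test_that("ANOVA from summaries is algebraically identical to raw data", {
  set.seed(44)
  for (i in 1:20) {
    groups <- lapply(sample(2:5, sample(2:4, 1), replace = TRUE),
                     function(n) stats::rnorm(n + 2, sample(0:3, 1)))
    raw <- anova_oneway(groups = groups)
    summ <- anova_oneway(summaries = data.frame(
      mean = vapply(groups, mean, 0),
      sd = vapply(groups, stats::sd, 0),
      n = vapply(groups, length, 0L)
    ))
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
    # reference: classical equal-variance F test
    ref <- stats::oneway.test(
      v ~ g,
      data = data.frame(v = unlist(groups),
                        g = factor(rep(seq_along(groups),
                                       lengths(groups)))),
      var.equal = TRUE
    )
    expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(45)
  x <- stats::rnorm(12)
  y <- stats::rnorm(9, 0.8)
  f <- anova_oneway(groups = list(x, y))$statistic
  t2 <- unname(stats::t.test(x, y, var.equal = TRUE)$statistic)^2
  expect_equal(f, t2, tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs are flagged", {
  expect_warning(res <- anova_oneway(groups = list(rep(2, 4), rep(2, 5))),
                 "zero within-group variance")
  expect_true(is.na(res$p_value))
  expect_error(anova_oneway(summaries = data.frame(mean = 1:2, sd = c(1, 1),
                                                   n = c(1, 5))),
               "n >= 2")
  expect_error(anova_oneway(groups = list(1:3)), "2 groups")
})
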