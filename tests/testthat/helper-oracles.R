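# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# AUC as the tie-corrected rank statistic P(X > Y) + P(X = Y)/2,
# by enumeration over every positive/negative pair.
oracle_auc <- function(scores, labels) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  wins <- outer(xs, ys, ">") + 0.5 * outer(xs, ys, "==")
  sum(wins) / (length(xs) * length(ys))
}

# Youden optimum by exhaustive search over midpoints plus sentinels,
# smallest cutoff on ties; rule: score >= cutoff => positive.
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cands <- c(-Inf, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  best_j <- -Inf
  best_cut <- NA_real_
  for (th in cands) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_cut <- th
    }
  }
  list(cutoff = best_cut, j = best_j)
}

# Two-sided Fisher p by full hypergeometric enumeration with fixed margins:
# sum the probabilities of all tables no more probable than the observed.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_min <- max(0, r1 + c1 - n)
  a_max <- min(r1, c1)
  probs <- vapply(a_min:a_max, function(a) {
    stats::dhyper(a, c1, n - c1, r1)
  }, 0)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# Exact two-sided Mann-Whitney p by enumerating all choose(n, nx)
# assignments of the pooled sample (valid without ties).
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x); ny <- length(y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(pooled), nx)
  u_null <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  center <- nx * ny / 2
  mean(abs(u_null - center) >= abs(u_obs - center) - 1e-12)
}

# Pearson chi-square by the definition sum (O - E)^2 / E.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Confusion matrix literal, built without the package's constructors.
new_cm <- function(tp, fp, tn, fn) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "tshfrax_cm")
}

# Small hand-built cohort exercising every schema field.
tiny_cohort <- function() {
  flags <- setNames(as.list(rep(FALSE, 7)), risk_flag_names())
  base <- tibble::tibble(
    id = c("a", "b", "c"),
    group = c("dtc", "dtc", "control"),
    sex = c("male", "female", "female"),
    age = c(48, 61, 50),
    height_cm = c(172, 158.5, 163),
    weight_kg = c(74, 60.1, 55),
    bmi = round(c(74, 60.1, 55) / (c(172, 158.5, 163) / 100)^2, 2),
    tsh = c(0.05, 1.2, 1.8),
    t_score = c(-2.61, -1.2, 0.4),
    postop_years = c(2.5, 0.8, NA),
    pmof_no_bmd = c(2.1, 3.4, 1.8),
    phf_no_bmd = c(0.2, 0.4, 0.1),
    pmof_with_bmd = c(4.5, 3.1, 1.5),
    phf_with_bmd = c(1.2, 0.3, 0.1)
  )
  base$prior_fracture <- c(TRUE, FALSE, FALSE)
  for (fl in setdiff(risk_flag_names(), "prior_fracture")) {
    base[[fl]] <- FALSE
  }
  base
}
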