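new_test_result <- function(method, statistic, df, p_value) {
  tibble::tibble(method = method, statistic = statistic,
                 df = df, p_value = p_value)
}

#' Pearson chi-square test of independence
#'
#' On an r x c contingency table of counts; no continuity correction by
#' default (the convention under which the published group comparisons
#' reproduce), switchable via `correct` for 2 x 2 tables.
#'
#' @param table Matrix of non-negative integer counts, at least 2 x 2.
#' @param correct Apply the Yates correction (2 x 2 only)? Default `FALSE`.
#' @return Tibble `method`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_independence(rbind(c(10, 17, 13), c(14, 6, 4)))
chi_square_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  check_count_table(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row/column total: expected counts undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  new_test_result("chi_square", unname(ht$statistic), unname(ht$parameter),
                  ht$p.value)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger
#' than the observed table's.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return Tibble `method`, `statistic` (odds-ratio estimate), `df` (NA),
#'   `p_value`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  check_count_table(table)
  if (!all(dim(table) == c(2, 2))) {
    stop("Fisher's exact test requires a 2x2 table", call. = FALSE)
  }
  ht <- stats::fisher.test(table)
  new_test_result("fisher_exact", unname(ht$estimate), NA_real_, ht$p.value)
}

check_count_table <- function(table) {
  if (any(!is.finite(table)) || any(table < 0) ||
      any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  invisible(table)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test with midrank tie handling. The p-value uses exact
#' enumeration when both samples have at most `exact_max` observations and
#' there are no ties, and the normal approximation with tie-corrected
#' variance otherwise (no continuity correction, mirroring common clinical
#' software).
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`); default
#'   `NULL` applies the sample-size rule.
#' @param exact_max Per-sample size limit for the default exact rule.
#' @return Tibble with `statistic` = U for `x` (number of (x, y) pairs with
#'   x > y, counting ties as 1/2).
#' @export
mann_whitney <- function(x, y, exact = NULL, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (is.null(exact)) {
    exact <- length(x) <= exact_max && length(y) <= exact_max
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  new_test_result("mann_whitney", unname(ht$statistic), NA_real_, ht$p.value)
}

#' One-way ANOVA from raw data or summary statistics
#'
#' Raw form: a list of numeric vectors, delegated to the classical
#' equal-variance F test. Summary form: a data frame with columns `mean`,
#' `sd`, `n` (one row per group); between-group and within-group sums of
#' squares are reconstructed algebraically, which is identical to the
#' raw-data ANOVA — so published group means/SDs/sizes suffice to
#' reproduce an F test without the raw data.
#'
#' @param groups List of numeric vectors (raw form); or `NULL`.
#' @param summaries Data frame with columns `mean`, `sd`, `n` (summary
#'   form); each group needs n >= 2.
#' @return Tibble `method`, `statistic` (F), `df` (string "df1,df2"),
#'   `p_value`. With zero within-group variance the p-value is `NA` with a
#'   warning (degenerate data).
#' @export
#' @examples
#' anova_oneway(summaries = data.frame(
#'   mean = c(44.38, 49.48, 54.35), sd = c(10.38, 12.47, 9.76),
#'   n = c(24, 23, 17)))
anova_oneway <- function(groups = NULL, summaries = NULL) {
  if (is.null(summaries)) {
    if (is.null(groups) || length(groups) < 2) {
      stop("need at least 2 groups", call. = FALSE)
    }
    summaries <- data.frame(
      mean = vapply(groups, mean, 0),
      sd   = vapply(groups, stats::sd, 0),
      n    = vapply(groups, length, 0L)
    )
  }
  if (nrow(summaries) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(summaries$n < 2)) {
    stop("summary-form ANOVA requires n >= 2 in every group", call. = FALSE)
  }
  m <- summaries$mean; s <- summaries$sd; n <- summaries$n
  k <- length(m); N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  if (msw == 0) {
    warning("zero within-group variance; F undefined", call. = FALSE)
    return(new_test_result("anova", NA_real_,
                           paste(df1, df2, sep = ","), NA_real_))
  }
  f <- (ssb / df1) / msw
  new_test_result("anova", f, paste(df1, df2, sep = ","),
                  stats::pf(f, df1, df2, lower.tail = FALSE))
}
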