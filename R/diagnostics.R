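#' Empirical ROC curve
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores, plus `-Inf` and `+Inf` sentinels; a subject is called
#' positive when its score is greater than or equal to the threshold
#' (higher predicted fracture risk points toward osteoporosis). This is
#' the convention of standard statistical software and is what makes
#' optimal cutoffs fall between adjacent one-decimal FRAX outputs.
#'
#' @param scores Numeric vector (risk probabilities, percent).
#' @param labels Binary vector (0/1 or logical); 1 = diseased
#'   (osteoporosis by the gold standard).
#' @return A `tshfrax_roc` tibble with columns `threshold` (ascending),
#'   `sensitivity`, `specificity`, and attributes `n_pos`, `n_neg`.
#' @export
#' @examples
#' build_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
build_roc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  labels <- as.integer(as.logical(labels))
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present (got ", n_pos, " positive, ",
         n_neg, " negative)", call. = FALSE)
  }
  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  sens <- vapply(thresholds, function(th) mean(scores[labels == 1] >= th), 0)
  spec <- vapply(thresholds, function(th) mean(scores[labels == 0] < th), 0)
  out <- tibble::tibble(threshold = thresholds, sensitivity = sens,
                        specificity = spec)
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  class(out) <- c("tshfrax_roc", class(out))
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the empirical ROC points. Mathematically this
#' equals the tie-corrected two-sample rank statistic
#' P(score_pos > score_neg) + P(score_pos = score_neg)/2, which the test
#' suite uses as an independent oracle.
#'
#' @param x A `tshfrax_roc` object, or a numeric score vector (then
#'   `labels` is required).
#' @param labels Binary labels when `x` is a score vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(x, labels = NULL) {
  roc <- if (inherits(x, "tshfrax_roc")) x else build_roc(x, labels)
  fpr <- 1 - roc$specificity
  sens <- roc$sensitivity
  # descending threshold order: fpr and sens both increase 0 -> 1
  ord <- order(roc$threshold, decreasing = TRUE)
  fpr <- fpr[ord]; sens <- sens[ord]
  sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
}

#' DeLong-style confidence interval for the AUC
#'
#' Placement-value (DeLong) variance estimate with a normal-theory
#' interval, truncated to \[0, 1\].
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param conf_level Confidence level, default 0.95.
#' @return Named vector `auc`, `lower`, `upper`, `se`.
#' @export
roc_auc_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(as.logical(labels))
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  if (length(xs) == 0 || length(ys) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(xs, function(a) mean(psi(a, ys)), 0)   # placements of cases
  v01 <- vapply(ys, function(b) mean(psi(xs, b)), 0)   # placements of controls
  auc <- mean(v10)
  var_auc <- stats::var(v10) / length(xs) + stats::var(v01) / length(ys)
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(auc = auc, lower = max(0, auc - z * se),
    upper = min(1, auc + z * se), se = se)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the curve's candidate
#' thresholds. Ties are broken toward the smallest cutoff, which among
#' tied candidates favours sensitivity; a message is emitted when a tie
#' occurs.
#'
#' @param roc A `tshfrax_roc` object.
#' @return One-row tibble `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "tshfrax_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  # near-ties within numerical noise count as ties
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1) {
    message("Youden tie among ", length(best),
            " candidate cutoffs; taking the smallest")
  }
  pick <- best[which.min(roc$threshold[best])]
  tibble::tibble(
    cutoff      = roc$threshold[pick],
    sensitivity = roc$sensitivity[pick],
    specificity = roc$specificity[pick],
    youden_j    = j[pick]
  )
}

#' Confusion matrix at a fixed cutoff
#'
#' Positive call is `score >= cutoff`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = diseased).
#' @param cutoff Finite threshold.
#' @return A `tshfrax_cm` list with integer counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  labels <- as.integer(as.logical(labels))
  pred <- scores >= cutoff
  cm <- list(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
             tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1))
  cm <- lapply(cm, as.integer)
  structure(cm, class = "tshfrax_cm")
}

new_confusion <- function(tp, fp, tn, fn) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "tshfrax_cm")
}

#' @export
print.tshfrax_cm <- function(x, ...) {
  cat("confusion matrix: TP", x$tp, " FP", x$fp, " TN", x$tn, " FN", x$fn,
      "\n")
  invisible(x)
}

#' Diagnostic metrics of a confusion matrix
#'
#' Sensitivity, specificity, and positive/negative predictive value.
#' Undefined ratios (0/0) are reported as `NA` with a warning, never as 0.
#'
#' @param cm A `tshfrax_cm` confusion matrix.
#' @param digits Decimal places for reporting (default 3, matching the
#'   usual presentation); use `NULL` for full precision.
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
cm_metrics <- function(cm, digits = 3) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  out <- c(
    sensitivity = ratio(cm$tp, cm$tp + cm$fn, "sensitivity"),
    specificity = ratio(cm$tn, cm$tn + cm$fp, "specificity"),
    ppv = ratio(cm$tp, cm$tp + cm$fp, "PPV"),
    npv = ratio(cm$tn, cm$tn + cm$fn, "NPV")
  )
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Reconstruct a confusion matrix from reported rates
#'
#' Inverts rounded sensitivity/specificity reporting: with known class
#' sizes, `tp` is the nearest integer to sensitivity * n_pos and `tn` the
#' nearest to specificity * n_neg. Useful to audit published diagnostic
#' tables for internal consistency. A warning is emitted when the rates
#' are not within rounding distance of an integer count.
#'
#' @param sensitivity,specificity Rates in \[0, 1\].
#' @param n_pos,n_neg Positive/negative class sizes (positive integers).
#' @return A `tshfrax_cm` confusion matrix.
#' @export
#' @examples
#' counts_from_rates(0.765, 0.638, 17, 47)
counts_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            n_pos >= 1, n_neg >= 1)
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  # a consistent report is a 3-decimal rounding of an integer-count ratio
  if (abs(sensitivity - tp / n_pos) > 5e-4 + 1e-12 ||
      abs(specificity - tn / n_neg) > 5e-4 + 1e-12) {
    warning("reported rates are inconsistent with integer counts",
            call. = FALSE)
  }
  fn <- n_pos - tp
  fp <- n_neg - tn
  if (fn < 0 || fp < 0) {
    stop("reconstructed counts are negative; inputs inconsistent",
         call. = FALSE)
  }
  new_confusion(tp, fp, tn, fn)
}

#' Full diagnostic summary for one score against the gold standard
#'
#' Convenience wrapper chaining [build_roc()], [roc_auc()],
#' [youden_cutoff()], [confusion_at()] and [cm_metrics()].
#'
#' @param scores Numeric scores (percent risk).
#' @param labels Binary labels (1 = osteoporosis).
#' @param digits Reporting precision for the rate metrics.
#' @return One-row tibble `auc`, `cutoff`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `youden_j`, `n_pos`, `n_neg`.
#' @export
diagnose <- function(scores, labels, digits = 3) {
  roc <- build_roc(scores, labels)
  yc <- youden_cutoff(roc)
  cutoff <- yc$cutoff
  # sentinel cutoffs (all-positive / all-negative rule) stay reportable
  eval_cut <- if (is.finite(cutoff)) cutoff else min(scores) - 1
  cm <- confusion_at(scores, labels, eval_cut)
  m <- cm_metrics(cm, digits = digits)
  tibble::tibble(
    auc = roc_auc(roc), cutoff = cutoff,
    sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
    ppv = m[["ppv"]], npv = m[["npv"]],
    youden_j = yc$youden_j,
    n_pos = attr(roc, "n_pos"), n_neg = attr(roc, "n_neg")
  )
}
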