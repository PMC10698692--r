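#' Default TSH age-weighting table
#'
#' Step table converting a serum TSH level (µIU/mL, numerically equal to
#' mIU/L) into years added to a patient's chronological age before a
#' fracture-risk calculation without BMD. Deeper TSH suppression maps to a
#' larger age penalty; euthyroid levels (TSH > 2) add nothing.
#'
#' The default intervals are:
#'
#' | TSH (µIU/mL)      | added years |
#' |-------------------|-------------|
#' | (0, 0.008)        | 20          |
#' | \[0.008, 0.1\]    | 15          |
#' | (0.1, 0.2\]       | 10          |
#' | (0.2, 0.3\]       | 8           |
#' | (0.3, 0.4\]       | 6           |
#' | (0.4, 0.5\]       | 4           |
#' | (0.5, 2\]         | 2           |
#' | (2, Inf)          | 0           |
#'
#' 0.008 µIU/mL is the assay detection limit; levels below it get the full
#' 20-year penalty. Boundaries left open by the clinical description
#' (exactly 0.008 and exactly 0.1) are closed on the lower-TSH side, i.e.
#' assigned the larger (more conservative) weight.
#'
#' @return A tibble with columns `lower`, `upper`, `lower_inclusive`,
#'   `upper_inclusive`, `added_years`, ordered by `lower`.
#' @seealso [tsh_added_years()], [effective_age()], [as_tsh_table()]
#' @export
#' @examples
#' default_tsh_table()
default_tsh_table <- function() {
  tab <- tibble::tibble(
    lower           = c(0, 0.008, 0.1, 0.2, 0.3, 0.4, 0.5, 2),
    upper           = c(0.008, 0.1, 0.2, 0.3, 0.4, 0.5, 2, Inf),
    lower_inclusive = c(FALSE, TRUE, rep(FALSE, 6)),
    upper_inclusive = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    added_years     = c(20L, 15L, 10L, 8L, 6L, 4L, 2L, 0L)
  )
  class(tab) <- c("tsh_weight_table", class(tab))
  tab
}

#' Build and validate a TSH weight table from a plain list
#'
#' Accepts the config-file representation: a list of entries with fields
#' `min`, `max`, `min_inclusive`, `max_inclusive`, `added_years` (as read
#' from YAML/JSON). The table is validated against the structural
#' invariants: intervals must be disjoint, jointly cover (0, Inf), and
#' `added_years` must be non-increasing as TSH rises.
#'
#' @param entries List of interval entries, or a data frame with columns
#'   `lower`, `upper`, `lower_inclusive`, `upper_inclusive`, `added_years`.
#' @return A validated `tsh_weight_table` tibble.
#' @export
as_tsh_table <- function(entries) {
  if (is.data.frame(entries)) {
    tab <- tibble::as_tibble(entries)
  } else {
    tab <- tibble::tibble(
      lower           = vapply(entries, function(e) as.numeric(e$min), 0),
      upper           = vapply(entries, function(e) as.numeric(e$max), 0),
      lower_inclusive = vapply(entries, function(e) isTRUE(e$min_inclusive), NA),
      upper_inclusive = vapply(entries, function(e) isTRUE(e$max_inclusive), NA),
      added_years     = vapply(entries, function(e) as.integer(e$added_years), 0L)
    )
  }
  tab <- tab[order(tab$lower), , drop = FALSE]
  validate_tsh_table(tab)
  class(tab) <- unique(c("tsh_weight_table", class(tab)))
  tab
}

validate_tsh_table <- function(tab) {
  required <- c("lower", "upper", "lower_inclusive", "upper_inclusive",
                "added_years")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("TSH weight table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) < 1) stop("TSH weight table is empty", call. = FALSE)
  if (any(tab$upper <= tab$lower)) {
    stop("TSH weight table has an interval with upper <= lower", call. = FALSE)
  }
  # Coverage of (0, Inf): first interval starts at 0, last is unbounded,
  # and consecutive intervals must abut with exactly one side closed.
  if (tab$lower[1] != 0 || is.finite(tab$upper[nrow(tab)])) {
    stop("TSH weight table must cover (0, Inf)", call. = FALSE)
  }
  if (nrow(tab) > 1) {
    for (i in seq_len(nrow(tab) - 1)) {
      if (tab$upper[i] != tab$lower[i + 1]) {
        stop("TSH weight table has a gap or overlap at ",
             format(tab$upper[i]), call. = FALSE)
      }
      closed <- tab$upper_inclusive[i] + tab$lower_inclusive[i + 1]
      if (closed != 1) {
        stop("boundary ", format(tab$upper[i]),
             " must belong to exactly one interval", call. = FALSE)
      }
    }
  }
  if (is.unsorted(rev(tab$added_years))) {
    stop("added_years must be non-increasing as TSH rises", call. = FALSE)
  }
  invisible(tab)
}

#' Years added to age for a given TSH level
#'
#' Looks up each TSH value in the weight table and returns the added years
#' of the unique interval containing it.
#'
#' @param tsh Numeric vector of TSH levels in µIU/mL; must be finite and > 0.
#' @param table A TSH weight table; defaults to [default_tsh_table()].
#' @return Integer vector of added years, same length as `tsh`.
#' @export
#' @examples
#' tsh_added_years(c(0.005, 0.05, 0.15, 1, 3))
tsh_added_years <- function(tsh, table = default_tsh_table()) {
  if (!is.numeric(tsh)) stop("tsh must be numeric", call. = FALSE)
  bad <- !is.finite(tsh) | tsh <= 0
  if (any(bad)) {
    stop("tsh must be finite and > 0 (offending value(s): ",
         paste(utils::head(format(tsh[bad]), 3), collapse = ", "), ")",
         call. = FALSE)
  }
  validate_tsh_table(table)
  out <- rep(NA_integer_, length(tsh))
  for (i in seq_len(nrow(table))) {
    lo_ok <- if (table$lower_inclusive[i]) tsh >= table$lower[i] else tsh > table$lower[i]
    hi_ok <- if (table$upper_inclusive[i]) tsh <= table$upper[i] else tsh < table$upper[i]
    out[lo_ok & hi_ok] <- table$added_years[i]
  }
  stopifnot(!anyNA(out))
  out
}

#' Effective (TSH-weighted) age
#'
#' Chronological age plus the TSH-dependent age penalty, capped so the
#' result stays inside the 40--90 year domain of FRAX-style calculators.
#' The cap is a modelling choice: the weighting can push an elderly,
#' deeply suppressed patient past 90, where 10-year fracture probabilities
#' are no longer defined by such tools.
#'
#' @param age Numeric vector of chronological ages in years, in \[20, 90\].
#' @param tsh Numeric vector of TSH levels (µIU/mL), recycled against `age`.
#' @param table TSH weight table.
#' @param cap Maximum effective age; default 90 years.
#' @return Numeric vector of effective ages (integer-valued when `age` is).
#' @export
#' @examples
#' effective_age(48, 0.05) # +15 years -> 63
#' effective_age(80, 0.005) # capped at 90
effective_age <- function(age, tsh, table = default_tsh_table(), cap = 90) {
  if (!is.numeric(age) || any(!is.finite(age))) {
    stop("age must be finite numeric", call. = FALSE)
  }
  if (any(age < 20 | age > 90)) {
    stop("age must be within [20, 90] years", call. = FALSE)
  }
  added <- tsh_added_years(tsh, table)
  eff <- pmin(age + added, cap)
  n_capped <- sum(age + added > cap)
  if (n_capped > 0) {
    message(n_capped, " effective age(s) capped at ", cap, " years")
  }
  eff
}
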