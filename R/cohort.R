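#' @name cohort
#' @title Cohort data model
#'
#' @description
#' A cohort is a tibble with one row per subject. Mandatory columns:
#' `id` (character), `group` (`"dtc"` or `"control"`), `sex` (`"male"` or
#' `"female"`), `age` (years), `tsh` (µIU/mL, > 0), `t_score` (hip DXA
#' T-score). Optional: `height_cm`, `weight_kg`, `bmi` (kg/m², derived from
#' height/weight when absent), `postop_years` (DTC only), seven boolean
#' clinical risk flags (see [risk_flag_names()]), and precomputed 10-year
#' fracture probabilities in percent (`pmof_no_bmd`, `phf_no_bmd`,
#' `pmof_with_bmd`, `phf_with_bmd`).
NULL

#' Names of the clinical risk-factor flags
#'
#' The FRAX-style binary risk factors carried per subject: prior fragility
#' fracture, parental hip fracture, current smoking, glucocorticoid use,
#' rheumatoid arthritis, secondary osteoporosis, and alcohol intake of three
#' or more units per day.
#'
#' @return Character vector of column names.
#' @export
risk_flag_names <- function() {
  c("prior_fracture", "parental_hip_fracture", "current_smoking",
    "glucocorticoid_use", "rheumatoid_arthritis", "secondary_osteoporosis",
    "alcohol_3plus_units")
}

risk_column_names <- function() {
  c("pmof_no_bmd", "phf_no_bmd", "pmof_with_bmd", "phf_with_bmd",
    "pmof_with_tsh", "phf_with_tsh")
}

mandatory_cohort_columns <- function() {
  c("id", "group", "sex", "age", "tsh", "t_score")
}

#' Validate a cohort table
#'
#' Enforces the per-subject invariants: TSH strictly positive, age in
#' \[20, 90\], sex and group levels, risks (when present) in \[0, 100\],
#' and BMI consistent with height/weight where all three are given
#' (tolerance 0.05 kg/m²; the explicit `bmi` wins with a warning beyond
#' that). Missing risk flags are filled as `FALSE` with a warning, and BMI
#' is derived from height/weight when absent.
#'
#' @param cohort A data frame following the cohort schema.
#' @return The validated (possibly completed) cohort tibble, invisibly
#'   modified: derived `bmi`, defaulted flags.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(mandatory_cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  if (!all(cohort$group %in% c("dtc", "control"))) {
    stop("group must be 'dtc' or 'control'", call. = FALSE)
  }
  if (!all(cohort$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(!is.finite(cohort$tsh) | cohort$tsh <= 0)) {
    stop("tsh must be finite and > 0 for every subject", call. = FALSE)
  }
  if (any(!is.finite(cohort$age) | cohort$age < 20 | cohort$age > 90)) {
    stop("age must lie in [20, 90] years", call. = FALSE)
  }
  # BMI: derive when absent, reconcile when redundant
  has_hw <- all(c("height_cm", "weight_kg") %in% names(cohort))
  if (!("bmi" %in% names(cohort))) {
    if (!has_hw) stop("cohort needs either bmi or height_cm + weight_kg",
                      call. = FALSE)
    cohort$bmi <- cohort$weight_kg / (cohort$height_cm / 100)^2
  } else if (has_hw) {
    derived <- cohort$weight_kg / (cohort$height_cm / 100)^2
    both <- is.finite(cohort$bmi) & is.finite(derived)
    off <- both & abs(cohort$bmi - derived) >= 0.05
    if (any(off)) {
      warning(sum(off), " subject(s) have bmi inconsistent with ",
              "height/weight beyond 0.05 kg/m^2; keeping the explicit bmi",
              call. = FALSE)
    }
    cohort$bmi[!is.finite(cohort$bmi) & is.finite(derived)] <-
      derived[!is.finite(cohort$bmi) & is.finite(derived)]
  }
  for (fl in risk_flag_names()) {
    if (!(fl %in% names(cohort))) {
      warning("risk flag '", fl, "' missing; defaulting to FALSE",
              call. = FALSE)
      cohort[[fl]] <- FALSE
    } else {
      if (anyNA(cohort[[fl]])) {
        warning("risk flag '", fl, "' has missing values; defaulting to FALSE",
                call. = FALSE)
        cohort[[fl]][is.na(cohort[[fl]])] <- FALSE
      }
      cohort[[fl]] <- as.logical(cohort[[fl]])
    }
  }
  for (rc in intersect(risk_column_names(), names(cohort))) {
    v <- cohort[[rc]]
    if (any(is.finite(v) & (v < 0 | v > 100))) {
      stop("risk column '", rc, "' outside [0, 100]", call. = FALSE)
    }
  }
  cohort
}

#' WHO bone-status classification from a DXA T-score
#'
#' Normal bone mass for T >= -1, osteopenia for -2.5 < T < -1, and
#' osteoporosis for T <= -2.5. The partition is total: every finite T-score
#' maps to exactly one status.
#'
#' @param t_score Numeric vector of DXA T-scores.
#' @return Factor with levels `normal`, `osteopenia`, `osteoporosis`.
#' @export
#' @examples
#' classify_bone_status(c(0, -1, -1.7, -2.5, -3.1))
classify_bone_status <- function(t_score) {
  if (!is.numeric(t_score) || any(!is.finite(t_score))) {
    stop("t_score must be finite numeric", call. = FALSE)
  }
  status <- ifelse(t_score >= -1, "normal",
                   ifelse(t_score <= -2.5, "osteoporosis", "osteopenia"))
  factor(status, levels = c("normal", "osteopenia", "osteoporosis"))
}

#' Bone-status composition of a cohort
#'
#' Counts and percentages (one decimal) of normal / osteopenic /
#' osteoporotic subjects.
#'
#' @param x A cohort tibble (uses its `t_score` column) or a numeric vector
#'   of T-scores.
#' @return Tibble with columns `status`, `n`, `percent`.
#' @export
classify_cohort <- function(x) {
  t_score <- if (is.data.frame(x)) x$t_score else x
  if (length(t_score) == 0) stop("empty cohort", call. = FALSE)
  status <- classify_bone_status(t_score)
  counts <- as.integer(table(status))
  pct <- round(100 * counts / length(status), 1)
  tibble::tibble(
    status  = factor(levels(status), levels = levels(status)),
    n       = counts,
    percent = pct
  )
}

#' Read a cohort CSV
#'
#' Reads a header-full CSV following the cohort schema (booleans coded 0/1,
#' decimal point `.`), applies an optional column mapping, and validates.
#' Cells that fail to parse as numbers are reported with their row index.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector mapping file column names
#'   to schema names, e.g. `c(TSH = "tsh")`.
#' @param keep_extra Keep columns outside the schema (`TRUE`, default) or
#'   drop them.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, col_map = NULL, keep_extra = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(raw))
    if (anyNA(idx)) {
      stop("col_map refers to absent column(s): ",
           paste(names(col_map)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    names(raw)[idx] <- unname(col_map)
  }
  missing_cols <- setdiff(mandatory_cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file '", path, "' lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- c("age", "height_cm", "weight_kg", "bmi", "tsh", "t_score",
                    "postop_years", risk_column_names())
  flag_cols <- risk_flag_names()
  out <- tibble::as_tibble(raw)
  parse_num <- function(col) {
    v <- out[[col]]
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0) {
      stop("column '", col, "': unparsable value '", v[bad[1]],
           "' at data row ", bad[1], call. = FALSE)
    }
    parsed
  }
  for (col in intersect(numeric_cols, names(out))) out[[col]] <- parse_num(col)
  for (col in intersect(flag_cols, names(out))) {
    v <- parse_num(col)
    if (any(!is.na(v) & !(v %in% c(0, 1)))) {
      stop("flag column '", col, "' must be coded 0/1", call. = FALSE)
    }
    out[[col]] <- v == 1
  }
  if (!keep_extra) {
    known <- c(mandatory_cohort_columns(), "height_cm", "weight_kg", "bmi",
               "postop_years", flag_cols, risk_column_names())
    out <- out[, intersect(names(out), known), drop = FALSE]
  }
  validate_cohort(out)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: booleans are written as 0/1, missing values
#' as empty cells, UTF-8, header included. A write/read round trip
#' preserves all fields.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (fl in intersect(risk_flag_names(), names(out))) {
    out[[fl]] <- as.integer(out[[fl]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Summarize one cohort variable
#'
#' Continuous variables get n, sample mean, sample SD (n-1 denominator),
#' and median/Q1/Q3 by linear interpolation between order statistics
#' (R's default quantile type 7). Categorical variables get per-level
#' counts and percentages.
#'
#' @param cohort Cohort tibble (or any data frame).
#' @param variable Column name to summarize.
#' @param kind `"continuous"` or `"categorical"`.
#' @return For continuous: one-row tibble `n, mean, sd, median, q1, q3`.
#'   For categorical: tibble `level, n, percent`.
#' @export
summarize_variable <- function(cohort, variable,
                               kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!(variable %in% names(cohort))) {
    stop("no column '", variable, "' in cohort", call. = FALSE)
  }
  v <- cohort[[variable]]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    stop("variable '", variable, "' has no non-missing values", call. = FALSE)
  }
  if (kind == "continuous") {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(
      n = length(v), mean = mean(v), sd = stats::sd(v),
      median = q[2], q1 = q[1], q3 = q[3]
    )
  } else {
    counts <- table(v)
    tibble::tibble(
      level   = names(counts),
      n       = as.integer(counts),
      percent = round(100 * as.integer(counts) / length(v), 1)
    )
  }
}
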