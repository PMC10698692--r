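#' TSH stratification of a cohort
#'
#' Strata used in the TSH-gradient comparison: suppressed below the
#' detection-adjacent band (TSH < 0.1), the broad suppression-to-euthyroid
#' band (0.1 to 2, inclusive at both ends), and unsuppressed (TSH > 2).
#'
#' @param tsh Numeric TSH values (µIU/mL).
#' @param breaks Two ascending boundaries, default `c(0.1, 2)`.
#' @return Factor with levels `"<0.1"`, `"0.1-2"`, `">2"` (labels follow
#'   the supplied breaks).
#' @export
tsh_stratify <- function(tsh, breaks = c(0.1, 2)) {
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  labs <- c(paste0("<", breaks[1]),
            paste0(breaks[1], "-", breaks[2]),
            paste0(">", breaks[2]))
  out <- ifelse(tsh < breaks[1], labs[1],
                ifelse(tsh <= breaks[2], labs[2], labs[3]))
  factor(out, levels = labs)
}

#' Assemble a run configuration
#'
#' @param cohort A cohort tibble; or `NULL` to read from `input` or draw
#'   from `generator`.
#' @param input Path to a cohort CSV (used when `cohort` is `NULL`).
#' @param generator A [generator_config()] (used when both `cohort` and
#'   `input` are `NULL`; requires `seed`).
#' @param seed Integer seed for synthetic cohorts.
#' @param gold_threshold T-score at or below which a subject counts as
#'   osteoporotic (the gold standard); must be negative. Default -2.5.
#' @param modes Risk computation modes to evaluate.
#' @param risk_source `"surrogate"` or `"precomputed"`.
#' @param coefficients Surrogate coefficients.
#' @param tsh_table TSH weight table.
#' @param out_dir Optional output directory for the report files.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = NULL, input = NULL,
                       generator = generator_config(), seed = NULL,
                       gold_threshold = -2.5,
                       modes = c("no_bmd", "with_bmd", "with_tsh"),
                       risk_source = c("surrogate", "precomputed"),
                       coefficients = default_surrogate_coefficients(),
                       tsh_table = default_tsh_table(),
                       out_dir = NULL) {
  risk_source <- match.arg(risk_source)
  if (length(modes) < 1) stop("at least one mode required", call. = FALSE)
  modes <- match.arg(modes, c("no_bmd", "with_bmd", "with_tsh"),
                     several.ok = TRUE)
  if (!is.numeric(gold_threshold) || gold_threshold >= 0) {
    stop("gold_threshold must be a negative T-score", call. = FALSE)
  }
  structure(list(cohort = cohort, input = input, generator = generator,
                 seed = seed, gold_threshold = gold_threshold,
                 modes = modes, risk_source = risk_source,
                 coefficients = coefficients, tsh_table = tsh_table,
                 out_dir = out_dir),
            class = "run_config")
}

fmt_mean_sd <- function(v) {
  sprintf("%.2f ± %.2f", mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE))
}

fmt_median_iqr <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE,
                       na.rm = TRUE)
  sprintf("%.2f (%.2f to %.2f)", q[2], q[1], q[3])
}

fmt_n_pct <- function(flag) {
  sprintf("%d (%.1f%%)", sum(flag, na.rm = TRUE),
          100 * mean(flag, na.rm = TRUE))
}

# one comparison row across the levels of `by`
comparison_row <- function(data, variable, by,
                           kind = c("mean_sd", "median_iqr", "flag")) {
  kind <- match.arg(kind)
  v <- data[[variable]]
  groups <- split(v, by)
  fmt <- switch(kind, mean_sd = fmt_mean_sd, median_iqr = fmt_median_iqr,
                flag = fmt_n_pct)
  cells <- vapply(groups, fmt, "")
  res <- tryCatch({
    if (kind == "flag") {
      tab <- rbind(vapply(groups, function(g) sum(g, na.rm = TRUE), 0L),
                   vapply(groups, function(g) sum(!g, na.rm = TRUE), 0L))
      if (all(dim(tab) == c(2, 2)) &&
          any(suppressWarnings(stats::chisq.test(tab)$expected) < 5)) {
        fisher_exact(tab)
      } else {
        chi_square_independence(tab)
      }
    } else if (length(groups) == 2) {
      mann_whitney(groups[[1]], groups[[2]])
    } else {
      anova_oneway(groups = lapply(groups, function(g) g[!is.na(g)]))
    }
  }, error = function(e) new_test_result(NA_character_, NA_real_,
                                         NA_real_, NA_real_))
  row <- tibble::tibble(variable = variable, all = fmt(v))
  for (nm in names(cells)) row[[nm]] <- cells[[nm]]
  row$method <- res$method
  row$p_value <- round(res$p_value, 3)
  row
}

risk_mode_labels <- function(modes) {
  lab <- c(no_bmd = "without BMD", with_bmd = "with BMD",
           with_tsh = "with TSH")
  lab[modes]
}

#' Run the full bone-health analysis
#'
#' From a conforming cohort (given, read, or synthesised), attaches
#' per-mode fracture risks and emits the four analysis tables of a
#' TSH-suppression bone-health study:
#' \enumerate{
#'   \item bone-status groups (normal / osteopenia / osteoporosis) within
#'     the disease cohort, with group comparisons;
#'   \item disease vs control comparison;
#'   \item TSH-stratified comparison within the disease cohort;
#'   \item diagnostic performance (AUC, Youden cutoff, sensitivity,
#'     specificity, PPV, NPV) of every mode x endpoint score against the
#'     T-score gold standard;
#' }
#' plus the ROC point sets and a metadata record. If the gold standard is
#' single-class the diagnostic stage is skipped with a warning; the other
#' tables still run. With `out_dir` set the bundle is also written as
#' CSV/JSON files (byte-stable for a fixed seed).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list `cohort`, `bone_status`, `table1`, `table2`,
#'   `table3`, `table4`, `roc`, `metadata`.
#' @export
run_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$cohort)) {
    validate_cohort(config$cohort)
  } else if (!is.null(config$input)) {
    read_cohort(config$input)
  } else {
    if (is.null(config$seed)) {
      stop("a seed is required to draw a synthetic cohort", call. = FALSE)
    }
    generate_cohort(config$generator, seed = config$seed)
  }
  cohort <- attach_risks(cohort, modes = config$modes,
                         source = config$risk_source,
                         coefficients = config$coefficients,
                         tsh_table = config$tsh_table)
  dtc <- cohort[cohort$group == "dtc", , drop = FALSE]
  has_controls <- any(cohort$group == "control")

  bone_status <- classify_cohort(dtc)
  status <- classify_bone_status(dtc$t_score)

  risk_cols <- intersect(c(paste0("pmof_", config$modes),
                           paste0("phf_", config$modes)), names(dtc))

  # Table 1 analogue: by bone status, within the disease group
  t1_rows <- list(
    comparison_row(cbind(dtc, male = dtc$sex == "male"), "male", status,
                   "flag"),
    comparison_row(dtc, "age", status, "mean_sd"),
    comparison_row(dtc, "bmi", status, "mean_sd")
  )
  for (fl in risk_flag_names()) {
    t1_rows <- c(t1_rows, list(comparison_row(dtc, fl, status, "flag")))
  }
  if (!all(is.na(dtc$postop_years))) {
    t1_rows <- c(t1_rows,
                 list(comparison_row(dtc, "postop_years", status, "mean_sd")))
  }
  t1_rows <- c(t1_rows, list(comparison_row(dtc, "tsh", status,
                                            "median_iqr")))
  for (rc in risk_cols) {
    t1_rows <- c(t1_rows, list(comparison_row(dtc, rc, status,
                                              "median_iqr")))
  }
  table1 <- do.call(rbind, t1_rows)

  # Table 2 analogue: disease vs control
  table2 <- NULL
  if (has_controls) {
    grp <- factor(cohort$group, levels = c("dtc", "control"))
    t2_rows <- list(
      comparison_row(cbind(cohort, male = cohort$sex == "male"), "male",
                     grp, "flag"),
      comparison_row(cohort, "age", grp, "mean_sd"),
      comparison_row(cohort, "bmi", grp, "mean_sd")
    )
    for (rc in risk_cols) {
      t2_rows <- c(t2_rows, list(comparison_row(cohort, rc, grp,
                                                "median_iqr")))
    }
    t2_rows <- c(t2_rows, list(comparison_row(cohort, "t_score", grp,
                                              "median_iqr")))
    table2 <- do.call(rbind, t2_rows)
  }

  # Table 3 analogue: TSH strata within the disease group
  strata <- tsh_stratify(dtc$tsh)
  t3_rows <- lapply(c(risk_cols, "t_score"), function(v) {
    comparison_row(dtc, v, strata, "median_iqr")
  })
  table3 <- do.call(rbind, t3_rows)
  attr(table3, "stratum_n") <- as.integer(table(strata))

  # Table 4 analogue: diagnostic performance vs the gold standard
  labels <- as.integer(dtc$t_score <= config$gold_threshold)
  table4 <- NULL
  roc_curves <- list()
  if (length(unique(labels)) < 2) {
    warning("gold standard is single-class; skipping the diagnostic stage",
            call. = FALSE)
  } else {
    rows <- list()
    for (ep in c("pmof", "phf")) {
      for (mode in config$modes) {
        col <- paste0(ep, "_", mode)
        d <- diagnose(dtc[[col]], labels)
        d <- cbind(tibble::tibble(endpoint = toupper(sub("^p", "", ep)),
                                  mode = mode,
                                  score = risk_mode_labels(mode)), d)
        rows <- c(rows, list(d))
        roc_curves[[col]] <- build_roc(dtc[[col]], labels)
      }
    }
    table4 <- do.call(rbind, rows)
  }

  metadata <- list(
    package_version = as.character(utils::packageVersion("tshfrax")),
    seed = config$seed,
    n_dtc = nrow(dtc),
    n_control = sum(cohort$group == "control"),
    gold_threshold = config$gold_threshold,
    modes = config$modes,
    risk_source = config$risk_source
  )

  bundle <- list(cohort = cohort, bone_status = bone_status,
                 table1 = table1, table2 = table2, table3 = table3,
                 table4 = table4, roc = roc_curves, metadata = metadata)
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  invisible(bundle)
}

#' Write an analysis bundle to disk
#'
#' CSV per table, CSV per ROC curve, cohort CSV, and a JSON metadata
#' sidecar. Output is byte-stable for identical inputs.
#'
#' @param bundle As returned by [run_analysis()].
#' @param out_dir Directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x)) {
      utils::write.csv(as.data.frame(x), file.path(out_dir, name),
                       row.names = FALSE, quote = FALSE, na = "")
    }
  }
  write_cohort(bundle$cohort, file.path(out_dir, "cohort.csv"))
  wr(bundle$bone_status, "bone_status.csv")
  wr(bundle$table1, "table1_bone_status_groups.csv")
  wr(bundle$table2, "table2_case_control.csv")
  wr(bundle$table3, "table3_tsh_strata.csv")
  wr(bundle$table4, "table4_diagnostics.csv")
  for (nm in names(bundle$roc)) {
    wr(bundle$roc[[nm]], paste0("roc_", nm, ".csv"))
  }
  jsonlite::write_json(bundle$metadata,
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare diagnostic performance across computation modes
#'
#' Pairwise differences in AUC and in specificity at the respective Youden
#' cutoffs, per endpoint. When both the TSH-weighted and the plain
#' no-BMD mode are present, the expected ordering (TSH weighting trades
#' sensitivity for specificity, so its specificity should be the larger)
#' is checked and a warning emitted if violated -- a check, not a failure.
#'
#' @param table4 The diagnostic table from [run_analysis()].
#' @return Tibble `endpoint`, `mode_a`, `mode_b`, `d_auc`,
#'   `d_specificity` (a minus b).
#' @export
compare_modes <- function(table4) {
  if (is.null(table4) || length(unique(table4$mode)) < 2) {
    stop("need at least 2 evaluated modes", call. = FALSE)
  }
  rows <- list()
  for (ep in unique(table4$endpoint)) {
    sub <- table4[table4$endpoint == ep, , drop = FALSE]
    modes <- sub$mode
    for (i in seq_along(modes)) {
      for (j in seq_along(modes)) {
        if (i >= j) next
        rows <- c(rows, list(tibble::tibble(
          endpoint = ep, mode_a = modes[i], mode_b = modes[j],
          d_auc = sub$auc[i] - sub$auc[j],
          d_specificity = sub$specificity[i] - sub$specificity[j]
        )))
      }
    }
    if (all(c("with_tsh", "no_bmd") %in% modes)) {
      s_tsh <- sub$specificity[sub$mode == "with_tsh"]
      s_no <- sub$specificity[sub$mode == "no_bmd"]
      if (is.finite(s_tsh) && is.finite(s_no) && s_tsh <= s_no) {
        warning(ep, ": specificity of the TSH-weighted score (", s_tsh,
                ") does not exceed the unweighted no-BMD score (", s_no,
                ")", call. = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
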