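#' Default surrogate risk-model coefficients
#'
#' The true FRAX engine is proprietary; this package ships a documented
#' surrogate in its place: an additive logistic model per endpoint (major
#' osteoporotic fracture, hip fracture) over the same covariates a FRAX
#' entry uses. It is a stand-in with the correct qualitative behaviour --
#' risk rises with age and each clinical risk flag, falls with BMI and
#' T-score -- and carries no claim of equivalence to the real calculator.
#'
#' The T-score term is measured relative to -1 (the osteopenia threshold),
#' so a subject at the upper limit of normal bone mass gets no BMD
#' adjustment and the "with BMD" and "without BMD" modes agree there by
#' construction. Default magnitudes were chosen once so that the default
#' synthetic cohort's median risks land in the clinically typical ranges
#' for a middle-aged East Asian cohort (median 10-year MOF probability
#' around 2--3%, hip around 0.2--0.5%).
#'
#' @return Named list with elements `mof` and `hf`, each a named numeric
#'   vector of log-odds effects: `intercept`, `age` (per effective year),
#'   `female`, `bmi` (per kg/m²), `t_score` (per unit of T + 1), and one
#'   entry per risk flag.
#' @seealso [estimate_risk()], [validate_coefficients()]
#' @export
default_surrogate_coefficients <- function() {
  list(
    mof = c(intercept = -5.85, age = 0.055, female = 0.30, bmi = -0.03,
            t_score = -0.90,
            prior_fracture = 0.70, parental_hip_fracture = 0.50,
            current_smoking = 0.30, glucocorticoid_use = 0.60,
            rheumatoid_arthritis = 0.40, secondary_osteoporosis = 0.40,
            alcohol_3plus_units = 0.30),
    hf  = c(intercept = -9.10, age = 0.075, female = 0.20, bmi = -0.03,
            t_score = -1.20,
            prior_fracture = 0.80, parental_hip_fracture = 0.60,
            current_smoking = 0.40, glucocorticoid_use = 0.60,
            rheumatoid_arthritis = 0.40, secondary_osteoporosis = 0.50,
            alcohol_3plus_units = 0.40)
  )
}

#' Validate surrogate coefficient signs
#'
#' Risk must increase with age and every binary risk flag, and must not
#' increase with BMI or T-score. Violations indicate a mis-specified
#' coefficient file and raise an error.
#'
#' @param coefficients As returned by [default_surrogate_coefficients()]
#'   or read from a YAML/JSON config.
#' @return The coefficients, invisibly, if valid.
#' @export
validate_coefficients <- function(coefficients) {
  needed <- c("intercept", "age", "female", "bmi", "t_score",
              risk_flag_names())
  for (ep in c("mof", "hf")) {
    co <- coefficients[[ep]]
    if (is.null(co)) stop("coefficients lack endpoint '", ep, "'",
                          call. = FALSE)
    co <- unlist(co)
    missing_terms <- setdiff(needed, names(co))
    if (length(missing_terms) > 0) {
      stop("endpoint '", ep, "' lacks term(s): ",
           paste(missing_terms, collapse = ", "), call. = FALSE)
    }
    if (co[["age"]] <= 0) stop(ep, ": age effect must be > 0", call. = FALSE)
    if (co[["t_score"]] >= 0) stop(ep, ": t_score effect must be < 0",
                                   call. = FALSE)
    if (co[["bmi"]] > 0) stop(ep, ": bmi effect must be <= 0", call. = FALSE)
    flags_neg <- risk_flag_names()[co[risk_flag_names()] < 0]
    if (length(flags_neg) > 0) {
      stop(ep, ": risk-flag effect(s) must be >= 0: ",
           paste(flags_neg, collapse = ", "), call. = FALSE)
    }
  }
  invisible(coefficients)
}

#' Read surrogate coefficients from a YAML or JSON file
#'
#' @param path Config file; format inferred from the extension
#'   (`.yml`/`.yaml` vs `.json`).
#' @return Validated coefficients list.
#' @export
read_coefficients <- function(path) {
  co <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  co <- lapply(co, function(x) unlist(x))
  validate_coefficients(co)
  co
}

#' Estimate 10-year fracture probabilities for a cohort
#'
#' Applies the surrogate risk model under one of three computation modes:
#' \describe{
#'   \item{`no_bmd`}{age, sex, BMI and risk flags only; no T-score, no TSH
#'     weighting. The "FRAX without BMD" entry.}
#'   \item{`with_bmd`}{as `no_bmd` plus the T-score term.}
#'   \item{`with_tsh`}{as `no_bmd` but with the TSH-weighted
#'     [effective_age()] in place of chronological age; the T-score stays
#'     out. When TSH > 2 µIU/mL no years are added and this mode coincides
#'     exactly with `no_bmd`.}
#' }
#' Probabilities are the inverse-logit of the linear predictor, in percent,
#' reported at 0.1 percentage-point resolution -- the granularity of the
#' FRAX web tool, and the reason Youden cutoffs land on midpoints such as
#' 2.15 between adjacent observed values.
#'
#' @param cohort Cohort tibble (or a single-row record).
#' @param mode One of `"no_bmd"`, `"with_bmd"`, `"with_tsh"`.
#' @param coefficients Surrogate coefficients.
#' @param tsh_table TSH weight table (used by `with_tsh`).
#' @param age_cap Cap for the effective age, passed to [effective_age()].
#' @return Tibble with columns `pmof`, `phf` (percent, one decimal) and
#'   `mode`.
#' @export
estimate_risk <- function(cohort, mode = c("no_bmd", "with_bmd", "with_tsh"),
                          coefficients = default_surrogate_coefficients(),
                          tsh_table = default_tsh_table(), age_cap = 90) {
  mode <- match.arg(mode)
  validate_coefficients(coefficients)
  need <- switch(mode, no_bmd = character(0), with_bmd = "t_score",
                 with_tsh = "tsh")
  for (col in need) {
    if (!(col %in% names(cohort)) || anyNA(cohort[[col]])) {
      stop("mode '", mode, "' requires non-missing '", col, "'",
           call. = FALSE)
    }
  }
  age_used <- if (mode == "with_tsh") {
    effective_age(cohort$age, cohort$tsh, tsh_table, cap = age_cap)
  } else {
    cohort$age
  }
  one_endpoint <- function(co) {
    co <- unlist(co)
    lp <- co[["intercept"]] +
      co[["age"]] * age_used +
      co[["female"]] * (cohort$sex == "female") +
      co[["bmi"]] * cohort$bmi
    if (mode == "with_bmd") {
      lp <- lp + co[["t_score"]] * (cohort$t_score + 1)
    }
    for (fl in risk_flag_names()) {
      flag <- if (fl %in% names(cohort)) cohort[[fl]] else FALSE
      lp <- lp + co[[fl]] * as.numeric(flag)
    }
    round(100 * stats::plogis(lp), 1)
  }
  pmof <- one_endpoint(coefficients$mof)
  phf <- one_endpoint(coefficients$hf)
  if (any(phf > pmof)) {
    warning(sum(phf > pmof),
            " subject(s) with hip-fracture risk above MOF risk",
            call. = FALSE)
  }
  tibble::tibble(pmof = pmof, phf = phf, mode = mode)
}

#' Attach per-mode risk columns to a cohort
#'
#' Fills `pmof_<mode>` / `phf_<mode>` columns either from the surrogate
#' calculator or by passing through precomputed columns (the route used
#' when probabilities were obtained from the FRAX website and stored in
#' the input CSV). Provenance is recorded in the `risk_source` attribute.
#'
#' @param cohort Cohort tibble.
#' @param modes Character vector of modes to fill.
#' @param source `"surrogate"` (compute) or `"precomputed"` (require the
#'   matching columns in the input).
#' @inheritParams estimate_risk
#' @return The cohort with risk columns for every requested mode.
#' @export
attach_risks <- function(cohort,
                         modes = c("no_bmd", "with_bmd", "with_tsh"),
                         source = c("surrogate", "precomputed"),
                         coefficients = default_surrogate_coefficients(),
                         tsh_table = default_tsh_table(), age_cap = 90) {
  source <- match.arg(source)
  modes <- match.arg(modes, c("no_bmd", "with_bmd", "with_tsh"),
                     several.ok = TRUE)
  for (mode in modes) {
    pcol <- paste0("pmof_", mode)
    hcol <- paste0("phf_", mode)
    if (source == "precomputed") {
      missing_cols <- setdiff(c(pcol, hcol), names(cohort))
      if (length(missing_cols) > 0) {
        stop("precomputed risks requested but column(s) missing: ",
             paste(missing_cols, collapse = ", "), call. = FALSE)
      }
    } else {
      est <- estimate_risk(cohort, mode, coefficients, tsh_table, age_cap)
      cohort[[pcol]] <- est$pmof
      cohort[[hcol]] <- est$phf
    }
  }
  attr(cohort, "risk_source") <- source
  cohort
}
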