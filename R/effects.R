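# Normalisation of heterogeneous mortality-ratio measures (RR, SMR, HR) to a
# common log relative-risk scale, the input contract of the meta-regression.

VALID_MEASURES <- c("RR", "SMR", "HR")

#' Log-scale standard error from a ratio confidence interval
#'
#' Inverts a symmetric normal confidence interval on the log scale:
#' `(log(ci_upper) - log(ci_lower)) / (2 * z)`, where `z` is the two-sided
#' standard-normal quantile for `confidence_level`. This is the standard way
#' to recover a sampling standard error for a ratio measure reported only
#' with its confidence bounds.
#'
#' @param ci_lower,ci_upper Positive ratio bounds, `ci_lower <= ci_upper`.
#'   Vectorised.
#' @param confidence_level Coverage of the interval as a fraction
#'   (default 0.95).
#' @return Nonnegative log-scale standard error(s).
#' @export
#' @examples
#' se_from_ci(1.77, 3.14)        # an RR of 2.36 (95% CI 1.77 to 3.14)
#' se_from_ci(2.0, 2.0)          # degenerate interval -> 0
se_from_ci <- function(ci_lower, ci_upper, confidence_level = 0.95) {
  if (any(!is.finite(ci_lower)) || any(!is.finite(ci_upper)) ||
      any(ci_lower <= 0) || any(ci_upper <= 0))
    stop_input("confidence bounds must be finite and strictly positive")
  if (any(ci_upper < ci_lower))
    stop_input("ci_upper must be >= ci_lower")
  (log(ci_upper) - log(ci_lower)) / (2 * z_quantile(confidence_level))
}

#' Convert ratio effect measures to the log relative-risk scale
#'
#' Mortality ratios arrive as relative risks (RR), standardised mortality
#' ratios (SMR) or hazard ratios (HR). With a rare exposure (prevalence of
#' schizophrenia is around 0.3%) the three measures are numerically
#' near-identical, so the default `"rare-outcome-identity"` policy carries
#' SMRs and HRs over unchanged, tagging each converted value with its
#' measure of origin so the choice is auditable per row. The policy argument
#' is the hook for substituting published conversion formulas when their
#' auxiliary inputs (baseline risks, expected deaths) are available.
#'
#' The standard error is taken from an explicit `se` where given, otherwise
#' recovered from the confidence bounds via [se_from_ci()]. Rows with
#' neither are rejected (`NA` log value) with the reason recorded in the
#' `note` column.
#'
#' @param value Positive ratio point estimate(s).
#' @param ci_lower,ci_upper Positive confidence bounds (may be `NA` when
#'   `se` is supplied).
#' @param se Optional log-scale standard error(s), used in preference to the
#'   bounds when finite.
#' @param measure Measure tag(s): `"RR"`, `"SMR"` or `"HR"`.
#' @param confidence_level Coverage of the reported interval (default 0.95).
#' @param policy Conversion policy; only `"rare-outcome-identity"` is
#'   built in.
#' @return A data frame with columns `log_value`, `se`, `measure_origin` and
#'   `note` (empty string for accepted rows).
#' @export
#' @examples
#' convert_to_rr(2.36, 1.77, 3.14, measure = "RR")
#' convert_to_rr(3.0, 2.0, 4.5, measure = "HR")
convert_to_rr <- function(value, ci_lower = NA_real_, ci_upper = NA_real_,
                          se = NA_real_, measure = "RR",
                          confidence_level = 0.95,
                          policy = "rare-outcome-identity") {
  n <- max(length(value), length(ci_lower), length(ci_upper),
           length(se), length(measure))
  value <- rep_len(value, n)
  ci_lower <- rep_len(ci_lower, n)
  ci_upper <- rep_len(ci_upper, n)
  se <- rep_len(as.numeric(se), n)
  measure <- rep_len(toupper(as.character(measure)), n)

  if (!identical(policy, "rare-outcome-identity"))
    stop_input("unknown conversion policy '%s' (available: 'rare-outcome-identity')",
               policy)
  bad <- !(measure %in% VALID_MEASURES)
  if (any(bad))
    stop_input("unknown effect measure(s): %s (expected RR, SMR or HR)",
               paste(unique(measure[bad]), collapse = ", "))
  if (any(!is.finite(value) | value <= 0))
    stop_input("effect values must be finite and strictly positive")

  out <- data.frame(log_value = log(value), se = NA_real_,
                    measure_origin = measure, note = "",
                    stringsAsFactors = FALSE)
  have_se <- is.finite(se)
  if (any(have_se & se < 0))
    stop_input("explicit standard errors must be nonnegative")
  out$se[have_se] <- se[have_se]

  have_ci <- !have_se & is.finite(ci_lower) & is.finite(ci_upper)
  if (any(have_ci)) {
    ord <- have_ci & (ci_lower > value | ci_upper < value)
    if (any(ord))
      stop_input("point estimate outside its confidence bounds in row(s) %s",
                 paste(which(ord), collapse = ", "))
    out$se[have_ci] <- se_from_ci(ci_lower[have_ci], ci_upper[have_ci],
                                  confidence_level)
  }
  rejected <- !have_se & !have_ci
  if (any(rejected)) {
    out$log_value[rejected] <- NA_real_
    out$note[rejected] <- "rejected: no confidence interval and no standard error"
  }
  out
}

#' Read a study-level mortality-ratio table
#'
#' Reads a comma-separated table of extracted study estimates (header row;
#' columns `study_id`, `outcome`, `measure`, `value`, `ci_lower`,
#' `ci_upper`, optional `se`, `percent_female`, `age_lower`, `age_upper`,
#' `case_definition`, `population_type`, optional `period_start`,
#' `period_end`), converts every row to the log relative-risk scale and
#' attaches the age midpoint used for moderator modelling. The midpoint of a
#' closed integer-year band `[lower, upper]` is `(lower + upper + 1) / 2`;
#' an open-ended band (missing upper bound) uses `lower + 5`.
#'
#' Rows whose effect cannot be converted (no confidence interval and no
#' standard error) are dropped with a message naming the row; the dropped
#' rows are kept in the `"rejected"` attribute of the result.
#'
#' @param path Path to the CSV file.
#' @param confidence_level Coverage of reported intervals (default 0.95).
#' @return A data frame of study estimates with columns `study_id`,
#'   `outcome`, `log_value`, `se`, `measure_origin`, `percent_female`,
#'   `age_lower`, `age_upper`, `age_mid`, `case_definition` (0 =
#'   schizophrenia only, 1 = includes schizoaffective disorder),
#'   `population_type` (0 = inpatient and outpatient, 1 = inpatient only).
#' @export
read_study_table <- function(path, confidence_level = 0.95) {
  if (!file.exists(path)) stop_input("study table not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "outcome", "measure", "value",
                "percent_female", "age_lower", "age_upper",
                "case_definition", "population_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop_input("study table %s lacks column(s): %s", path,
               paste(missing_cols, collapse = ", "))
  for (col in c("ci_lower", "ci_upper", "se"))
    if (is.null(raw[[col]])) raw[[col]] <- NA_real_

  if (any(!is.finite(raw$value) | raw$value <= 0))
    stop_input("nonpositive or missing effect value in row(s) %s of %s",
               paste(which(!is.finite(raw$value) | raw$value <= 0),
                     collapse = ", "), path)

  conv <- convert_to_rr(raw$value, raw$ci_lower, raw$ci_upper, raw$se,
                        raw$measure, confidence_level)
  est <- data.frame(
    study_id = as.character(raw$study_id),
    outcome = as.character(raw$outcome),
    log_value = conv$log_value,
    se = conv$se,
    measure_origin = conv$measure_origin,
    percent_female = as.numeric(raw$percent_female),
    age_lower = as.numeric(raw$age_lower),
    age_upper = suppressWarnings(as.numeric(raw$age_upper)),
    case_definition = code_case_definition(raw$case_definition),
    population_type = code_population_type(raw$population_type),
    stringsAsFactors = FALSE
  )
  est$age_mid <- age_midpoint(est$age_lower, est$age_upper)
  if (any(est$percent_female < 0 | est$percent_female > 1, na.rm = TRUE))
    stop_input("percent_female must lie in [0, 1] (fractions, not percent)")

  drop <- is.na(est$log_value)
  if (any(drop)) {
    message(sprintf("dropping %d row(s) of %s: %s", sum(drop), path,
                    paste(sprintf("row %d (%s)", which(drop),
                                  conv$note[drop]), collapse = "; ")))
  }
  kept <- est[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "rejected") <- est[drop, , drop = FALSE]
  kept
}

# map case-definition labels to 0 (schizophrenia only) / 1 (+ schizoaffective)
code_case_definition <- function(x) {
  if (is.numeric(x)) {
    if (any(!x %in% c(0, 1))) stop_input("case_definition codes must be 0 or 1")
    return(as.numeric(x))
  }
  lab <- tolower(trimws(as.character(x)))
  out <- ifelse(grepl("schizoaffective|\\bsa\\b|combined", lab), 1,
         ifelse(grepl("schizophrenia|\\bsz\\b|only", lab), 0, NA_real_))
  if (any(is.na(out)))
    stop_input("unrecognised case_definition label(s): %s",
               paste(unique(lab[is.na(out)]), collapse = ", "))
  out
}

# map population-type labels to 0 (inpatient and outpatient) / 1 (inpatient only)
code_population_type <- function(x) {
  if (is.numeric(x)) {
    if (any(!x %in% c(0, 1))) stop_input("population_type codes must be 0 or 1")
    return(as.numeric(x))
  }
  lab <- tolower(trimws(as.character(x)))
  out <- ifelse(grepl("outpatient|combined|both", lab), 0,
         ifelse(grepl("inpatient", lab), 1, NA_real_))
  if (any(is.na(out)))
    stop_input("unrecognised population_type label(s): %s",
               paste(unique(lab[is.na(out)]), collapse = ", "))
  out
}
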