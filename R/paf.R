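# Population attributable fractions and the attributable-burden calculus
# against the absence-of-exposure counterfactual, including the
# explained/unexplained decomposition of all-cause attributable burden.

#' Population attributable fraction for a binary exposure
#'
#' The two-category comparative-risk-assessment form
#' \deqn{PAF = \frac{P\,(RR - 1)}{P\,(RR - 1) + 1}}
#' where `P` is exposure prevalence and `RR` the relative risk of the
#' outcome in the exposed. The counterfactual is complete absence of
#' exposure. `RR < 1` is permitted and yields a negative PAF (a protective
#' exposure); such values are flagged with a warning rather than clipped.
#'
#' @param prevalence Exposure prevalence, fraction(s) in \[0, 1\].
#' @param rr Relative risk(s), strictly positive. Recycled against
#'   `prevalence`; matrices are accepted (e.g. strata by draws).
#' @param warn_negative Warn when any PAF is negative (default `TRUE`).
#' @return PAF(s), same shape as the broader of the two inputs.
#' @export
#' @examples
#' compute_paf(0.0032, 4.08)   # rare exposure, strong risk: ~0.0098
#' compute_paf(0.1, 1)         # null relative risk: 0
compute_paf <- function(prevalence, rr, warn_negative = TRUE) {
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop_input("relative risks must be finite and strictly positive")
  if (any(prevalence < 0 | prevalence > 1))
    stop_input("prevalence must lie in [0, 1]")
  excess <- prevalence * (rr - 1)
  paf <- excess / (excess + 1)
  if (warn_negative && any(paf < 0))
    warning(sprintf("%d PAF value(s) are negative (RR < 1); kept unclipped",
                    sum(paf < 0)), call. = FALSE)
  paf
}

#' Attributable burden in one stratum
#'
#' Multiplies the stratum PAF by the stratum's total burden (deaths or
#' YLLs); the result has the units of the burden envelope.
#'
#' @param paf PAF(s), typically from [compute_paf()].
#' @param burden Nonnegative burden count(s).
#' @return Attributable burden, `paf * burden`.
#' @export
attributable_stratum <- function(paf, burden) {
  if (any(!is.finite(burden)) || any(burden < 0))
    stop_input("burden must be finite and nonnegative")
  paf * burden
}

#' Attributable burden as a proportion of total burden
#'
#' @param attributable Attributable count(s).
#' @param total Total burden count(s) of the same outcome.
#' @return `attributable / total`; a zero total yields `NA` with a warning
#'   (undefined proportion) rather than an error.
#' @export
proportion_of_total <- function(attributable, total) {
  out <- attributable / total
  zero <- total == 0
  if (any(zero)) {
    warning(sprintf("%d proportion(s) undefined (total burden 0); returned NA",
                    sum(zero)), call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Decompose all-cause attributable burden into explained and unexplained
#'
#' The explained burden is the sum of the outcome-specific attributable
#' burdens; the unexplained burden is the all-cause attributable burden
#' minus the explained burden. With Monte-Carlo draws the identity
#' `all_cause = explained + unexplained` holds exactly within every draw;
#' summaries (means, quantiles) are taken afterwards. Draws in which the
#' explained burden exceeds the all-cause attributable burden are kept as
#' negative unexplained values (never clipped) and their count is reported
#' via a message.
#'
#' @param all_cause Numeric vector of all-cause attributable burden (one
#'   value per draw; length 1 for point estimates).
#' @param outcomes List of numeric vectors of outcome-specific attributable
#'   burden, each the same length as `all_cause`.
#' @return A list of class `"cra_decomposition"` with per-draw vectors
#'   `all_cause`, `explained`, `unexplained` and `percent_explained`
#'   (explained / all_cause, a fraction).
#' @export
#' @examples
#' d <- decompose_explained(368883, list(48223))
#' d$unexplained   # 320660
decompose_explained <- function(all_cause, outcomes) {
  stopifnot(is.numeric(all_cause), is.list(outcomes), length(outcomes) >= 1)
  n <- length(all_cause)
  lens <- vapply(outcomes, length, integer(1))
  if (any(lens != n))
    stop_input("draw-length mismatch: all_cause has %d draw(s), outcomes have %s",
               n, paste(lens, collapse = ", "))
  explained <- Reduce(`+`, outcomes)
  unexplained <- all_cause - explained
  neg <- sum(unexplained < 0)
  if (neg > 0)
    message(sprintf(
      "explained burden exceeds all-cause attributable burden in %d of %d draw(s); kept as negative unexplained",
      neg, n))
  structure(list(all_cause = all_cause,
                 explained = explained,
                 unexplained = unexplained,
                 percent_explained = explained / all_cause),
            class = "cra_decomposition")
}
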