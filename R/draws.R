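# Monte-Carlo uncertainty propagation: seeded draws on transformed scales,
# deterministic pipeline application per draw, and mean / 95% UI summaries.
#
# The sampling design follows the draw-based GBD convention: 1000
# independent samples are pulled from the (transformed-scale normal)
# distribution of every input quantity, the deterministic pipeline is
# applied to each sample, and reported estimates are the mean and the 2.5th
# and 97.5th quantiles of the resulting samples. Quantities bounded in
# (0, 1) (prevalence, death proportions of their envelope) are sampled on
# the logit scale; positive quantities (YLLs, population, relative risks)
# on the log scale.

transform_spec <- function(transform) {
  switch(transform,
    identity = list(f = identity, inv = identity,
                    domain = function(x) rep(TRUE, length(x))),
    log = list(f = log, inv = exp, domain = function(x) x > 0),
    logit = list(f = logit, inv = inv_logit,
                 domain = function(x) x > 0 & x < 1),
    stop_input("unknown transform '%s'", transform))
}

new_draw_set <- function(draws, quantity, transform, seed, n_draws = ncol(draws)) {
  structure(draws, quantity = quantity, transform = transform, seed = seed,
            n_draws = n_draws, class = c("draw_set", class(draws)))
}

#' Sample a quantity from its 95% uncertainty interval
#'
#' Draws are independent normal on the transformed scale, centred at
#' `transform(value)` with standard deviation `(transform(ui_upper) -
#' transform(ui_lower)) / (2 * 1.959964)` — i.e. the interval is read as a
#' symmetric 95% normal interval on that scale — then back-transformed.
#' Back-transformed draws therefore always respect the transform's domain:
#' logit draws stay in (0, 1), log draws stay positive. A value sitting on
#' the transform's boundary (0 or 1 for logit, 0 for log) has no
#' finite transformed location; the draw set degenerates to that constant
#' with a warning. Zero-width intervals also yield constants.
#'
#' @param value Point value(s), one per stratum.
#' @param ui_lower,ui_upper 95% uncertainty bounds bracketing `value`.
#' @param transform `"identity"`, `"log"` or `"logit"`.
#' @param n_draws Number of samples per stratum (default 1000).
#' @param seed Integer seed; equal seeds give bit-identical draw sets.
#' @param quantity Label carried on the result.
#' @return A `draw_set`: a `length(value)` by `n_draws` matrix with
#'   attributes `quantity`, `transform`, `seed`, `n_draws`.
#' @export
#' @examples
#' d <- draw_from_ui(0.0032, 0.0027, 0.0037, "logit", n_draws = 500, seed = 7)
#' range(d)   # stays inside (0, 1)
draw_from_ui <- function(value, ui_lower, ui_upper,
                         transform = c("identity", "log", "logit"),
                         n_draws = 1000, seed, quantity = "quantity") {
  transform <- match.arg(transform)
  stopifnot(n_draws >= 1)
  m <- length(value)
  if (length(ui_lower) != m || length(ui_upper) != m)
    stop_input("value, ui_lower and ui_upper must have equal length")
  if (any(ui_lower > value | ui_upper < value, na.rm = TRUE))
    stop_input("uncertainty bounds must bracket the value")
  tr <- transform_spec(transform)

  boundary <- !tr$domain(value)
  if (any(boundary & (ui_upper > ui_lower)))
    warning(sprintf(
      "%d value(s) lie on the boundary of the %s transform's domain; returning constant draws for those strata",
      sum(boundary & (ui_upper > ui_lower)), transform), call. = FALSE)
  ok <- !boundary & tr$domain(ui_lower) & tr$domain(ui_upper)

  mu <- ifelse(ok, tr$f(value), 0)
  sdv <- ifelse(ok, (tr$f(ui_upper) - tr$f(ui_lower)) / (2 * z_quantile(0.95)), 0)
  draws <- with_seed(seed,
    matrix(stats::rnorm(m * n_draws, mean = mu, sd = sdv), m, n_draws))
  draws <- tr$inv(draws)
  # boundary and zero-width strata are exact constants (no transform
  # round-trip error)
  const <- !ok | sdv == 0
  draws[const, ] <- rep(value[const], n_draws)
  new_draw_set(draws, quantity, transform, seed, n_draws)
}

#' Apply a deterministic pipeline to every draw
#'
#' Takes aligned draw sets (equal numbers of strata rows and draws) and a
#' function of one draw — a named list with one numeric vector per input —
#' and applies it column-by-column, so any computation expressed on point
#' values propagates uncertainty unchanged. With every input degenerate
#' (constant draws) the output equals the deterministic pipeline exactly.
#'
#' @param inputs Named list of draw-set matrices (or plain matrices).
#' @param fun Function taking a named list of per-draw vectors and
#'   returning a numeric vector (or scalar) of fixed length.
#' @param quantity Label for the output draw set.
#' @return A `draw_set` of the outputs, one column per draw.
#' @export
propagate_draws <- function(inputs, fun, quantity = "derived") {
  stopifnot(is.list(inputs), length(inputs) >= 1)
  nds <- vapply(inputs, ncol, integer(1))
  if (length(unique(nds)) != 1)
    stop_input("inputs have mismatched draw counts: %s",
               paste(nds, collapse = ", "))
  nd <- nds[[1]]
  one <- function(j) fun(lapply(inputs, function(mm) mm[, j]))
  first <- one(1)
  out <- matrix(NA_real_, length(first), nd)
  out[, 1] <- first
  if (nd > 1) for (j in 2:nd) out[, j] <- one(j)
  new_draw_set(out, quantity, "identity", NA_integer_, nd)
}

#' Summarise draws to mean and 95% uncertainty interval
#'
#' Returns, per row, the mean and the 2.5th and 97.5th quantiles of the
#' draws on the natural (back-transformed) scale. Quantiles use linear
#' interpolation between order statistics (R's default type 7 definition).
#'
#' @param draws A `draw_set`, matrix (rows summarised separately) or
#'   numeric vector of draws.
#' @return A data frame with columns `mean`, `lower`, `upper`.
#' @export
summarise_draws <- function(draws) {
  m <- if (is.matrix(draws)) draws else matrix(draws, nrow = 1)
  if (ncol(m) < 1) stop_input("no draws to summarise")
  # rows with non-finite draws (e.g. a proportion with zero denominator)
  # summarise to NA rather than erroring
  q <- t(apply(m, 1, function(x) {
    if (any(!is.finite(x))) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(x), stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE))
  }))
  data.frame(mean = q[, 1], lower = q[, 2], upper = q[, 3])
}
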