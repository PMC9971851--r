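# Internal helpers shared across modules.

# two-sided standard-normal quantile for a given confidence level
z_quantile <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  stats::qnorm(1 - (1 - level) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

# Evaluate `code` under a temporary RNG state so draws are reproducible
# without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a deterministic child seed from a root seed and a label
#'
#' Every randomised quantity in a run draws under its own child seed, derived
#' from the run's root seed and the quantity's label. Adding a quantity to a
#' run therefore never perturbs the draws of the others, and any single
#' quantity can be re-drawn in isolation.
#'
#' @param root_seed Integer root seed of the run.
#' @param label Character label naming the quantity (e.g. `"deaths:ihd"`).
#' @return An integer in `[1, 2^31 - 1)`, suitable for `set.seed()`.
#' @export
#' @examples
#' child_seed(42, "prevalence")
child_seed <- function(root_seed, label) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.finite(root_seed))
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(root_seed) %% 2147483629 * 48271 + h + 1) %% 2147483629 + 1)
}

# small deterministic hash of an R object, for run manifests
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
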