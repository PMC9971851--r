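# Multilevel random-effects meta-regression of log relative risks, with
# estimates nested within studies, moderator selection by backward
# elimination on AIC, and age-sex-specific RR prediction.
#
# Model: log_effect = X beta + u_study + v_estimate + e, with
#   u_study    ~ N(0, tau2_study), shared by all estimates of a study,
#   v_estimate ~ N(0, tau2_estimate), one per estimate,
#   e          ~ N(0, se^2), the known sampling error of each estimate.
# Fitting is delegated to metafor::rma.mv (the standard engine for this
# model class); moderator comparison during elimination uses maximum
# likelihood, because AIC comparisons across fixed-effect structures are
# invalid under REML, and the final model is refit by REML.

META_TERMS <- c("percent_female", "age", "age_sex",
                "case_definition", "population_type")
# tie-break order during elimination: drop the covariate listed later, so
# main effects are preserved longest
DROP_ORDER <- c("age_sex", "case_definition", "population_type",
                "percent_female", "age")

canonical_covariates <- function(covariates) {
  covariates <- unique(covariates)
  unknown <- setdiff(covariates, META_TERMS)
  if (length(unknown))
    stop_input("unknown covariate(s): %s (available: %s)",
               paste(unknown, collapse = ", "), paste(META_TERMS, collapse = ", "))
  META_TERMS[META_TERMS %in% covariates]
}

validate_estimates <- function(estimates, outcome = NULL) {
  stopifnot(is.data.frame(estimates))
  if (!is.null(outcome) && !is.null(estimates$outcome))
    estimates <- estimates[estimates$outcome == outcome, , drop = FALSE]
  need <- setdiff(c("study_id", "log_value", "se"), names(estimates))
  if (length(need))
    stop_input("estimates lack column(s): %s", paste(need, collapse = ", "))
  if (nrow(estimates) < 1) stop_input("no estimates to pool")
  if (is.null(estimates$age_mid) && !is.null(estimates$age_lower))
    estimates$age_mid <- age_midpoint(estimates$age_lower, estimates$age_upper)
  for (col in c("percent_female", "age_mid", "case_definition", "population_type"))
    if (is.null(estimates[[col]])) estimates[[col]] <- 0
  if (any(!is.finite(estimates$log_value)) || any(!is.finite(estimates$se)))
    stop_input("non-finite log effects or standard errors")
  if (any(estimates$se < 0)) stop_input("standard errors must be nonnegative")
  if (any(estimates$percent_female < 0 | estimates$percent_female > 1))
    stop_input("percent_female must lie in [0, 1]")
  estimates
}

# centred design matrix; centres are the estimate-weighted means recorded on
# the fitted model, so the intercept is the pooled both-sex, mean-age log RR
build_design <- function(dat, covariates, pf_centre, age_centre) {
  X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "intercept"))
  pf <- dat$percent_female - pf_centre
  ag <- dat$age_mid - age_centre
  for (cv in covariates) {
    col <- switch(cv,
                  percent_female = pf,
                  age = ag,
                  age_sex = pf * ag,
                  case_definition = as.numeric(dat$case_definition),
                  population_type = as.numeric(dat$population_type))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  X
}

#' Fit the multilevel meta-regression for one health outcome
#'
#' Pools log relative-risk estimates with a three-level model: a random
#' intercept per study plus a random effect per estimate (estimates nested
#' within studies), on top of each estimate's known sampling variance.
#' Continuous moderators are centred — age at the estimate-weighted mean
#' age midpoint, sex (as percent female) at its estimate-weighted mean —
#' so the exponentiated intercept is the pooled both-sex relative risk at
#' the mean age.
#'
#' @param estimates Data frame of study estimates (see
#'   [read_study_table()] / [generate_studies()]): columns `study_id`,
#'   `log_value`, `se`, and the moderator columns `percent_female`,
#'   `age_mid` (or `age_lower`/`age_upper`), `case_definition`,
#'   `population_type`.
#' @param covariates Moderators to include, a subset of
#'   `c("percent_female", "age", "age_sex", "case_definition",
#'   "population_type")`. `"age_sex"` is the product of the two centred
#'   continuous terms and requires both mains.
#' @param outcome Optional outcome label; when the data carry an `outcome`
#'   column, rows are filtered to it and the label is stored on the model.
#' @param method `"REML"` (default, for reported fits) or `"ML"` (for AIC
#'   comparison of fixed-effect structures).
#' @param struct `"nested"` (study and estimate variance components) or
#'   `"study"` (study-level only).
#' @param centres Optional list `list(percent_female =, age =)` overriding
#'   the centring constants (used when predicting from a refit).
#' @return An object of class `"cra_meta"`: coefficients and their
#'   covariance, variance components `tau2_study` and `tau2_estimate`, the
#'   (restricted) log-likelihood, `aic = -2 logLik + 2 (p + q)` counting
#'   `p` fixed coefficients and `q` estimated variance components, counts
#'   of studies and estimates, retained covariates and centring constants.
#' @export
fit_meta <- function(estimates, covariates = character(), outcome = NULL,
                     method = c("REML", "ML"), struct = c("nested", "study"),
                     centres = NULL) {
  method <- match.arg(method)
  struct <- match.arg(struct)
  dat <- validate_estimates(estimates, outcome)
  covariates <- canonical_covariates(covariates)
  if ("age_sex" %in% covariates &&
      !all(c("percent_female", "age") %in% covariates))
    stop_input("the age-sex interaction requires both main effects")

  pf_centre <- centres$percent_female %||% mean(dat$percent_female)
  age_centre <- centres$age %||% mean(dat$age_mid)
  X <- build_design(dat, covariates, pf_centre, age_centre)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_input("design matrix is rank deficient; collinear column(s): %s",
               paste(bad, collapse = ", "))
  }

  y <- dat$log_value
  vi <- dat$se^2
  k <- nrow(dat)
  n_studies <- length(unique(dat$study_id))

  if (k == 1) {
    # a single estimate: variance components are unidentifiable and fixed
    # at zero; the pooled value is the estimate itself
    beta <- c(intercept = y)
    vb <- matrix(vi, 1, 1, dimnames = list("intercept", "intercept"))
    ll <- stats::dnorm(0, sd = sqrt(max(vi, .Machine$double.eps)), log = TRUE)
    tau2 <- c(0, 0)
    q <- 0L
  } else {
    dat$.est_id <- seq_len(k)
    random <- if (struct == "nested") ~ 1 | study_id / .est_id else ~ 1 | study_id
    args <- list(yi = y, V = vi, random = random, data = dat,
                 method = method, test = "z", sparse = FALSE)
    if (ncol(X) > 1) args$mods <- X[, -1, drop = FALSE]
    # boundary estimates (variance components near 0) can defeat a single
    # optimizer; walk a small ladder before giving up
    controls <- list(list(),
                     list(optimizer = "optim", optmethod = "Nelder-Mead"),
                     list(optimizer = "optim", optmethod = "BFGS"),
                     list(sigma2.init = rep(1e-4, if (struct == "nested") 2 else 1)))
    fit <- NULL
    errs <- character()
    for (ctrl in controls) {
      fit <- tryCatch(do.call(metafor::rma.mv, c(args, list(control = ctrl))),
                      error = function(e) {
                        errs <<- c(errs, conditionMessage(e)); NULL
                      })
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop_input("meta-regression failed to converge: %s",
                 paste(unique(errs), collapse = " | "))
    beta <- as.vector(fit$beta)
    names(beta) <- colnames(X)
    vb <- fit$vb
    dimnames(vb) <- list(colnames(X), colnames(X))
    ll <- as.numeric(stats::logLik(fit))
    tau2 <- if (struct == "nested") fit$sigma2 else c(fit$sigma2, 0)
    q <- length(fit$sigma2)
  }

  p <- length(beta)
  structure(list(
    outcome = outcome %||% unique(as.character(dat$outcome %||% NA))[1],
    coefficients = beta,
    vcov = vb,
    tau2_study = tau2[1],
    tau2_estimate = tau2[2],
    retained_covariates = covariates,
    loglik = ll,
    aic = -2 * ll + 2 * (p + q),
    method = method,
    struct = struct,
    n_studies = n_studies,
    n_estimates = k,
    pf_centre = pf_centre,
    age_centre = age_centre
  ), class = "cra_meta")
}

#' @export
print.cra_meta <- function(x, digits = 4, ...) {
  cat(sprintf("Multilevel meta-regression (%s%s): %d estimates in %d studies\n",
              x$method, if (!is.na(x$outcome %||% NA)) paste0(", ", x$outcome) else "",
              x$n_estimates, x$n_studies))
  cat(sprintf("tau2 (study) = %.*g, tau2 (estimate) = %.*g, AIC = %.*g\n",
              digits, x$tau2_study, digits, x$tau2_estimate, digits, x$aic))
  se <- sqrt(diag(x$vcov))
  print(round(data.frame(estimate = x$coefficients, se = se,
                         row.names = names(x$coefficients)), digits))
  rr <- exp(x$coefficients[["intercept"]])
  cat(sprintf("pooled RR (both sexes, mean age): %.*g\n", digits, rr))
  invisible(x)
}

#' Backward elimination of moderators on AIC
#'
#' Starting from the full covariate set, iteratively removes the covariate
#' whose removal most lowers the AIC, until no removal lowers it. Model
#' comparison uses maximum-likelihood fits; the final model is refit by
#' REML. The age-sex interaction is never retained without both main
#' effects, and mains are not removal candidates while the interaction is
#' present. Exact AIC ties (within 1e-8) are broken by dropping the
#' covariate listed later in (interaction, case definition, population
#' type, percent female, age), which keeps main effects in the model
#' longest. Covariates in `forced` are never removed (used e.g. to retain
#' population type as a bias control despite weak support).
#'
#' @inheritParams fit_meta
#' @param full_covariates Starting covariate set (default: all five).
#' @param forced Covariates exempt from elimination.
#' @return The final REML [fit_meta()] model, with an `"elimination"`
#'   attribute tracing each step (covariate removed and resulting AIC).
#' @export
backward_eliminate <- function(estimates,
                               full_covariates = META_TERMS,
                               forced = character(),
                               outcome = NULL,
                               struct = c("nested", "study")) {
  struct <- match.arg(struct)
  current <- canonical_covariates(full_covariates)
  forced <- canonical_covariates(forced)
  if (length(setdiff(forced, current)))
    stop_input("forced covariate(s) not in the full set: %s",
               paste(setdiff(forced, current), collapse = ", "))
  aic_of <- function(cvs)
    fit_meta(estimates, cvs, outcome, method = "ML", struct = struct)$aic
  current_aic <- aic_of(current)
  trace <- data.frame(step = 0L, removed = "", aic = current_aic,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    candidates <- setdiff(current, forced)
    if ("age_sex" %in% current)
      candidates <- setdiff(candidates, c("percent_female", "age"))
    if (!length(candidates)) break
    aics <- vapply(candidates,
                   function(cv) aic_of(setdiff(current, cv)), numeric(1))
    best <- min(aics)
    if (best >= current_aic - 1e-8) break
    tied <- candidates[aics <= best + 1e-8]
    drop <- tied[which.max(match(tied, DROP_ORDER))]
    current <- setdiff(current, drop)
    current_aic <- aic_of(current)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = drop,
                                     aic = current_aic))
  }
  final <- fit_meta(estimates, current, outcome, method = "REML",
                    struct = struct)
  attr(final, "elimination") <- trace
  final
}

#' Predict a relative risk for a covariate profile
#'
#' Evaluates `exp(x' beta)` at the requested profile, with a delta-method
#' 95% uncertainty interval on the log scale from the coefficient
#' covariance. Unspecified inputs sit at their reference levels: the
#' centring point for the continuous moderators (so the default prediction
#' is the pooled both-sex RR at the mean age) and 0 for the binary
#' moderators. Supplying a non-reference value for a covariate that was
#' eliminated from the model triggers a warning and reference-level
#' substitution.
#'
#' @param model A [fit_meta()] / [backward_eliminate()] model.
#' @param percent_female Fraction female of the target stratum (0 male,
#'   1 female, 0.5 both sexes); default: the model's centring value.
#' @param age_mid Age midpoint in years; default: the model's centring
#'   value. Vectorised (recycled against `percent_female`).
#' @param case_definition,population_type Binary moderator levels
#'   (default 0, the reference).
#' @param level Interval coverage (default 0.95).
#' @return Data frame with columns `percent_female`, `age_mid`, `rr`,
#'   `ui_lower`, `ui_upper`.
#' @export
predict_rr <- function(model, percent_female = NULL, age_mid = NULL,
                       case_definition = 0, population_type = 0,
                       level = 0.95) {
  stopifnot(inherits(model, "cra_meta"))
  ret <- model$retained_covariates
  pf <- percent_female %||% model$pf_centre
  am <- age_mid %||% model$age_centre
  n <- max(length(pf), length(am), length(case_definition),
           length(population_type))
  pf <- rep_len(pf, n); am <- rep_len(am, n)
  cd <- rep_len(case_definition, n); pt <- rep_len(population_type, n)

  warn_sub <- function(name, vals, ref) {
    if (!(name %in% ret) && any(vals != ref)) {
      warning(sprintf(
        "'%s' is not in the model; prediction uses its reference level", name),
        call. = FALSE)
    }
  }
  warn_sub("percent_female", pf, model$pf_centre)
  warn_sub("age", am, model$age_centre)
  warn_sub("case_definition", cd, 0)
  warn_sub("population_type", pt, 0)

  prof <- data.frame(percent_female = pf, age_mid = am,
                     case_definition = cd, population_type = pt)
  X <- build_design(prof, ret, model$pf_centre, model$age_centre)
  lp <- drop(X %*% model$coefficients)
  se <- sqrt(pmax(rowSums((X %*% model$vcov) * X), 0))
  z <- z_quantile(level)
  data.frame(percent_female = pf, age_mid = am,
             rr = exp(lp), ui_lower = exp(lp - z * se),
             ui_upper = exp(lp + z * se))
}

#' Tabulate fitted meta-regression models
#'
#' One row per coefficient per outcome (estimate, standard error, 95%
#' bounds on the log scale) plus a `pooled_rr` row per outcome carrying the
#' exponentiated intercept and its interval — the content of a final-model
#' report table.
#'
#' @param models Named list of [fit_meta()] models (names = outcomes).
#' @return A data frame with columns `outcome`, `n_studies`,
#'   `n_estimates`, `term`, `estimate`, `se`, `ci_lower`, `ci_upper`.
#' @export
meta_report <- function(models) {
  stopifnot(is.list(models), length(models) >= 1)
  z <- z_quantile(0.95)
  rows <- lapply(names(models), function(oc) {
    m <- models[[oc]]
    se <- sqrt(diag(m$vcov))
    co <- data.frame(outcome = oc, n_studies = m$n_studies,
                     n_estimates = m$n_estimates,
                     term = names(m$coefficients),
                     estimate = unname(m$coefficients), se = unname(se),
                     ci_lower = unname(m$coefficients - z * se),
                     ci_upper = unname(m$coefficients + z * se))
    rr <- predict_rr(m)
    rbind(co, data.frame(outcome = oc, n_studies = m$n_studies,
                         n_estimates = m$n_estimates, term = "pooled_rr",
                         estimate = rr$rr, se = NA_real_,
                         ci_lower = rr$ui_lower, ci_upper = rr$ui_upper))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
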