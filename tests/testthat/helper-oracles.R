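# Independent oracles and small fixture builders used across the suite.

# Restricted log-likelihood of the nested-random-effects model, written
# directly from the marginal covariance V = tau2_study * S + (tau2_est +
# se^2) I (S_ij = 1 when rows i, j share a study), independently of the
# package's fitting route. Additive constants are dropped; only
# comparisons between (tau2_study, tau2_est) points matter.
reml_loglik_oracle <- function(tau2_study, tau2_est, y, X, se2, study) {
  n <- length(y)
  V <- tau2_study * (outer(study, study, `==`) * 1)
  diag(V) <- diag(V) + tau2_est + se2
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(-Inf)
  W <- chol2inv(cv)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  r <- y - X %*% beta
  ld_V <- 2 * sum(log(diag(cv)))
  ld_X <- as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
  -0.5 * (ld_V + ld_X + drop(crossprod(r, W %*% r)))
}

# minimal study-estimate frame: one row per element of log_value
make_est <- function(log_value, se, study_id = seq_along(log_value),
                     percent_female = 0.5, age_mid = 50,
                     case_definition = 0, population_type = 0) {
  data.frame(study_id = as.character(study_id), log_value = log_value,
             se = se, percent_female = percent_female, age_mid = age_mid,
             case_definition = case_definition,
             population_type = population_type,
             stringsAsFactors = FALSE)
}

# single-outcome scenario with configurable true effects (other outcomes
# removed so the world stays small in tests that do not need them)
one_outcome_truth <- function(rr = 2.5, sex_log_rr = 0, age_slope = 0,
                              tau2_study = 0.05, tau2_estimate = 0.01, ...) {
  scenario_truth(
    outcomes = list(ihd = list(rr = rr, sex_log_rr = sex_log_rr,
                               age_slope = age_slope,
                               deaths_total = 9.1e6, ylls_total = 1.77e8,
                               male_share_deaths = 0.55)),
    tau2_study = tau2_study, tau2_estimate = tau2_estimate, ...)
}

canonical_band_table <- function(value, quantity = "prevalence",
                                 rel = 0.1, bands = default_age_bands()) {
  grid <- expand.grid(sex = c("female", "male"), age_group = bands,
                      stringsAsFactors = FALSE)
  v <- rep_len(value, nrow(grid))
  stratum_table(data.frame(grid, value = v, ui_lower = v * (1 - rel),
                           ui_upper = v * (1 + rel)), quantity)
}
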