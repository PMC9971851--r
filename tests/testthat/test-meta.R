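# Multilevel meta-regression: degenerate inputs, pooling identities,
# REML optimality against the grid oracle, moderator selection, prediction.

test_that("a single estimate pools to itself with zero heterogeneity", {
  m <- fit_meta(make_est(log(2.5), 0.2))
  expect_equal(unname(m$coefficients), log(2.5))
  expect_equal(m$tau2_study, 0)
  expect_equal(m$tau2_estimate, 0)
  expect_equal(m$n_studies, 1)
})

test_that("identical estimates across studies give the common value and no heterogeneity", {
  m <- fit_meta(make_est(rep(0.7, 5), rep(0.2, 5)))
  expect_equal(unname(m$coefficients), 0.7, tolerance = 1e-8)
  expect_equal(m$tau2_study, 0, tolerance = 1e-8)
  expect_equal(m$tau2_estimate, 0, tolerance = 1e-8)
})

test_that("with equal SEs and no heterogeneity the pooled value is the plain mean", {
  # spread of the estimates is tiny relative to their SEs, so the REML
  # variance components go to zero and GLS reduces to the arithmetic mean
  y <- c(0.68, 0.70, 0.72, 0.70)
  m <- fit_meta(make_est(y, rep(0.3, 4)))
  expect_equal(m$tau2_study + m$tau2_estimate, 0, tolerance = 1e-6)
  expect_equal(unname(m$coefficients), mean(y), tolerance = 1e-6)
})

test_that("the intercept-only pooled estimate stays inside the hull of the data", {
  withr::with_seed(42, {
    for (i in 1:15) {
      k <- sample(3:10, 1)
      y <- rnorm(k, 0.8, 0.5)
      se <- runif(k, 0.05, 0.4)
      m <- fit_meta(make_est(y, se, study_id = sample(1:4, k, replace = TRUE)))
      expect_gte(unname(m$coefficients), min(y) - 1e-10)
      expect_lte(unname(m$coefficients), max(y) + 1e-10)
    }
  })
})

test_that("returned variance components maximise the restricted likelihood (grid oracle)", {
  withr::with_seed(7, {
    for (i in 1:3) {
      est <- make_est(rnorm(8, 0.9, 0.35), runif(8, 0.1, 0.3),
                      study_id = rep(1:4, each = 2))
      m <- fit_meta(est)
      X <- matrix(1, 8, 1)
      ll_fit <- reml_loglik_oracle(m$tau2_study, m$tau2_estimate,
                                   est$log_value, X, est$se^2, est$study_id)
      grid_s <- seq(0, 2 * max(m$tau2_study, 0.05), length.out = 20)
      grid_e <- seq(0, 2 * max(m$tau2_estimate, 0.05), length.out = 20)
      ll_grid <- outer(grid_s, grid_e, Vectorize(function(a, b)
        reml_loglik_oracle(a, b, est$log_value, X, est$se^2, est$study_id)))
      expect_gte(ll_fit, max(ll_grid) - 1e-6)
    }
  })
})

test_that("moderator recovery matches the generator's truth on one instance", {
  truth <- one_outcome_truth(rr = 2.5, age_slope = -0.02, sex_log_rr = 0.3)
  st <- generate_studies(truth, "ihd", 40, 2, se_range = c(0.05, 0.15), seed = 11)
  m <- fit_meta(st, c("percent_female", "age"))
  se <- sqrt(diag(m$vcov))
  expect_lt(abs(m$coefficients[["intercept"]] - log(2.5)), 3 * se[1])
  expect_lt(abs(m$coefficients[["percent_female"]] - 0.3), 3 * se[2])
  expect_lt(abs(m$coefficients[["age"]] - (-0.02)), 3 * se[3])
})

test_that("rank-deficient designs fail naming the collinear column", {
  est <- make_est(rnorm(6, 0.7, 0.1), rep(0.2, 6), case_definition = 1)
  expect_error(fit_meta(est, "case_definition"), "case_definition")
  expect_error(fit_meta(make_est(0.5, 0.1), "age_sex"), "main effects")
  expect_error(fit_meta(est, "height"), "unknown covariate")
})

test_that("backward elimination keeps a covariate whose removal raises AIC", {
  truth <- one_outcome_truth(age_slope = -0.05, tau2_study = 0.01,
                             tau2_estimate = 0.005)
  st <- generate_studies(truth, "ihd", 30, 2, se_range = c(0.05, 0.1), seed = 3)
  m <- backward_eliminate(st, full_covariates = "age")
  expect_identical(m$retained_covariates, "age")
  expect_identical(m$method, "REML")  # final refit is REML after ML comparisons
})

test_that("elimination prunes null covariates and keeps a strong age effect", {
  # under the null each covariate survives only when its LRT exceeds the
  # AIC penalty of 2 (about 16% each), so most replicates end with at most
  # one or two covariates and pruning removes the majority on average
  truth0 <- one_outcome_truth(age_slope = 0)
  n_ret <- integer(40)
  for (r in 1:40) {
    st <- generate_studies(truth0, "ihd", 30, 2, seed = 1000 + r)
    n_ret[r] <- length(backward_eliminate(st)$retained_covariates)
  }
  expect_lte(mean(n_ret), 2.2)          # derived expectation ~1.3
  expect_gte(mean(n_ret == 0), 0.15)    # intercept-only well above a no-pruning baseline

  truth1 <- one_outcome_truth(age_slope = -0.05)
  kept <- logical(30)
  for (r in 1:30) {
    st <- generate_studies(truth1, "ihd", 30, 2, seed = 2000 + r)
    kept[r] <- "age" %in% backward_eliminate(st)$retained_covariates
  }
  expect_gte(mean(kept), 0.9)
})

test_that("forced covariates survive elimination", {
  truth0 <- one_outcome_truth(age_slope = 0)
  st <- generate_studies(truth0, "ihd", 20, 2, seed = 5)
  m <- backward_eliminate(st, forced = "population_type")
  expect_true("population_type" %in% m$retained_covariates)
})

test_that("predict_rr evaluates the fitted linear predictor", {
  m0 <- fit_meta(make_est(log(2.89), 0.073))
  p <- predict_rr(m0)
  expect_equal(p$rr, 2.89)
  expect_true(p$ui_lower <= p$rr && p$rr <= p$ui_upper)

  truth <- one_outcome_truth(rr = 2.5, age_slope = -0.03, sex_log_rr = 0.2)
  st <- generate_studies(truth, "ihd", 30, 2, seed = 9)
  m <- fit_meta(st, c("percent_female", "age"))
  # at the centring point the prediction is the exponentiated intercept
  expect_equal(predict_rr(m)$rr, exp(m$coefficients[["intercept"]]))
  # closed form of the fitted age trend: +10 years scales the RR by exp(10 b)
  b <- m$coefficients[["age"]]
  r0 <- predict_rr(m, age_mid = m$age_centre)$rr
  r10 <- predict_rr(m, age_mid = m$age_centre + 10)$rr
  expect_equal(r10 / r0, exp(10 * b), tolerance = 1e-10)
  # non-reference level of an eliminated covariate: warn and substitute
  expect_warning(p2 <- predict_rr(m, case_definition = 1), "reference")
  expect_equal(p2$rr, predict_rr(m)$rr)
})

test_that("meta_report tabulates coefficients and pooled RRs per outcome", {
  truth <- one_outcome_truth()
  st <- generate_studies(truth, "ihd", 10, 2, seed = 2)
  models <- list(ihd = fit_meta(st, "age", outcome = "ihd"))
  rep_ <- meta_report(models)
  expect_setequal(rep_$term, c("intercept", "age", "pooled_rr"))
  rr_row <- rep_[rep_$term == "pooled_rr", ]
  expect_equal(rr_row$estimate,
               exp(models$ihd$coefficients[["intercept"]]))
  expect_true(all(rep_$n_studies == 10) && all(rep_$n_estimates == 20))
})
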