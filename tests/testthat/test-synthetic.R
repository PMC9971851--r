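# Synthetic-data generator: internal consistency of the stored ground
# truth, determinism, limits, and the distributional contract.

test_that("ground truth is mutually consistent (PAF recomputable from parts)", {
  truth <- paper_like_scenario()
  for (oc in names(truth$outcomes)) {
    o <- truth$outcomes[[oc]]
    expect_equal(o$paf,
                 compute_paf(truth$strata$prevalence, o$rr,
                             warn_negative = FALSE))
    expect_equal(o$totals$attrib_deaths, sum(o$paf * o$deaths))
  }
  s <- truth$summary
  expect_equal(s$unexplained_deaths,
               s$all_cause_attrib_deaths - s$explained_deaths)
  # population-weighted all-age prevalence hits the calibration target exactly
  g <- truth$strata
  expect_equal(sum(g$prevalence * g$population) / sum(g$population),
               0.0032, tolerance = 1e-12)
})

test_that("the all-cause envelope dominates the outcome envelopes per stratum", {
  truth <- paper_like_scenario()
  sum_d <- Reduce(`+`, lapply(truth$outcomes, `[[`, "deaths"))
  expect_true(all(sum_d <= truth$all_cause$deaths))
  expect_error(
    scenario_truth(all_cause = list(rr = 2.89, sex_log_rr = 0,
                                    age_slope = -0.02, deaths_total = 1e4,
                                    ylls_total = 1e5,
                                    male_share_deaths = 0.54)),
    "exceed")
})

test_that("study generation is deterministic and respects the noise-free limit", {
  truth <- paper_like_scenario()
  a <- generate_studies(truth, "ihd", 10, 2, seed = 77)
  b <- generate_studies(truth, "ihd", 10, 2, seed = 77)
  expect_identical(a, b)
  expect_false(identical(a, generate_studies(truth, "ihd", 10, 2, seed = 78)))

  quiet <- one_outcome_truth(rr = 2.5, age_slope = -0.02, sex_log_rr = 0.3,
                             tau2_study = 0, tau2_estimate = 0)
  st <- generate_studies(quiet, "ihd", 6, 2, se_range = c(1e-6, 1e-6), seed = 1)
  lp <- log(2.5) + 0.3 * (st$percent_female - 0.5) - 0.02 * (st$age_mid - 50)
  expect_equal(st$log_value, lp, tolerance = 1e-5)
  expect_error(generate_studies(quiet, "ihd", 6, 2, se_range = numeric(0)),
               "se_range")
  expect_error(generate_studies(quiet, "nope", 6, 2), "unknown outcome")
})

test_that("generated studies round-trip through the raw-effect CSV contract", {
  truth <- paper_like_scenario()
  st <- generate_studies(truth, "diabetes", 5, 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(st[, c("study_id", "outcome", "measure", "value", "ci_lower",
                   "ci_upper", "percent_female", "age_lower", "age_upper",
                   "case_definition", "population_type")],
            path, row.names = FALSE)
  back <- read_study_table(path)
  expect_equal(back$log_value, st$log_value, tolerance = 1e-12)
  expect_equal(back$se, st$se, tolerance = 1e-9)
  expect_equal(back$age_mid, st$age_mid)
})

test_that("generated log effects are indistinguishable from their normal model", {
  # all noise components are normal, so residuals about the true linear
  # predictor are exactly normal; a 1%-level test should reject at chance
  truth <- paper_like_scenario()
  o <- truth$outcomes$ihd$params
  rejections <- 0L
  for (s in 1:100) {
    st <- generate_studies(truth, "ihd", 25, 2, seed = 4000 + s)
    lp <- log(o$rr) + o$sex_log_rr * (st$percent_female - 0.5) +
      o$age_slope * (st$age_mid - 50)
    if (stats::shapiro.test(st$log_value - lp)$p.value < 0.01)
      rejections <- rejections + 1L
  }
  expect_lte(rejections, 6)  # binomial(100, 0.01): P(X > 6) < 1e-5
})

test_that("a zero-prevalence world yields zero attributable burden end to end", {
  truth <- scenario_truth(prevalence_all_age = 0)
  expect_equal(truth$outcomes$ihd$totals$attrib_deaths, 0)
  res <- cra_burden(generate_world(truth), uncertainty = FALSE)
  expect_equal(res$attributable$deaths, rep(0, 4))
  expect_equal(res$decomposition$mean[
    res$decomposition$component == "explained"], c(0, 0))
})

test_that("attributable burden scales almost linearly in a small prevalence", {
  t1 <- scenario_truth(prevalence_all_age = 0.0016)
  t2 <- scenario_truth(prevalence_all_age = 0.0032)
  r <- t2$outcomes$ihd$totals$attrib_deaths /
    t1$outcomes$ihd$totals$attrib_deaths
  expect_equal(r, 2, tolerance = 0.01)
})

test_that("world generation with observation noise stays valid and seeded", {
  truth <- paper_like_scenario()
  w1 <- generate_world(truth, seed = 5, observation_noise = TRUE)
  w2 <- generate_world(truth, seed = 5, observation_noise = TRUE)
  expect_identical(w1$prevalence$value, w2$prevalence$value)
  expect_false(identical(w1$prevalence$value, truth$strata$prevalence))
  expect_s3_class(w1$prevalence, "stratum_table")   # still validates
  expect_true(all(w1$prevalence$value > 0 & w1$prevalence$value < 1))
})

test_that("a world written to disk reads back equal", {
  truth <- paper_like_scenario()
  world <- generate_world(truth)
  dir <- withr::local_tempdir()
  write_world(world, dir)
  back <- read_world(dir)
  expect_equal(back$prevalence$value, world$prevalence$value)
  expect_equal(back$outcomes$ihd$deaths$value, world$outcomes$ihd$deaths$value)
  expect_equal(back$all_cause$rr$value, world$all_cause$rr$value)
  expect_setequal(names(back$outcomes), c("ihd", "stroke", "diabetes"))
})
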