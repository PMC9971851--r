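# Monte-Carlo draws on transformed scales, propagation, summaries.

test_that("zero-width intervals give constant draws and constant summaries", {
  d <- draw_from_ui(0.5, 0.5, 0.5, "logit", n_draws = 100, seed = 1)
  expect_true(all(d == 0.5))
  s <- summarise_draws(d)
  expect_equal(unlist(s), c(mean = 0.5, lower = 0.5, upper = 0.5))
})

test_that("equal seeds give bit-identical draw sets", {
  a <- draw_from_ui(c(0.1, 0.2), c(0.08, 0.15), c(0.12, 0.26), "logit",
                    n_draws = 256, seed = 99)
  b <- draw_from_ui(c(0.1, 0.2), c(0.08, 0.15), c(0.12, 0.26), "logit",
                    n_draws = 256, seed = 99)
  expect_identical(unclass(a), unclass(b))
  c_ <- draw_from_ui(c(0.1, 0.2), c(0.08, 0.15), c(0.12, 0.26), "logit",
                     n_draws = 256, seed = 100)
  expect_false(identical(unclass(a), unclass(c_)))
})

test_that("draws respect the transform's domain and recover the interval", {
  d <- draw_from_ui(0.0032, 0.0027, 0.0037, "logit", n_draws = 1e5, seed = 4)
  expect_true(all(d > 0 & d < 1))
  q <- quantile(d, c(0.025, 0.975), type = 7)
  expect_equal(unname(q[1]), 0.0027, tolerance = 0.02)  # 2% relative
  expect_equal(unname(q[2]), 0.0037, tolerance = 0.02)
  expect_equal(mean(d), 0.0032, tolerance = 0.02)

  dl <- draw_from_ui(1000, 800, 1250, "log", n_draws = 1e5, seed = 5)
  expect_true(all(dl > 0))
  expect_equal(unname(quantile(dl, 0.975, type = 7)), 1250, tolerance = 0.02)
})

test_that("boundary values degenerate to constants with a warning", {
  expect_warning(d <- draw_from_ui(0, 0, 0.1, "log", n_draws = 50, seed = 1),
                 "boundary")
  expect_true(all(d == 0))
  expect_warning(d2 <- draw_from_ui(c(1, 0.5), c(0.9, 0.4), c(1, 0.6),
                                    "logit", n_draws = 50, seed = 1),
                 "boundary")
  expect_true(all(d2[1, ] == 1))
  expect_false(all(d2[2, ] == 0.5))
  expect_error(draw_from_ui(0.5, 0.6, 0.7, "logit", 10, seed = 1), "bracket")
})

test_that("quantile summaries use linear interpolation between order statistics", {
  s <- summarise_draws(matrix(1:1000, nrow = 1))
  # type-7 closed form on 1..1000: 1 + p * 999
  expect_equal(s$lower, 25.975)
  expect_equal(s$upper, 975.025)
  expect_equal(s$mean, 500.5)
})

test_that("propagation of degenerate draws equals the deterministic pipeline", {
  prev <- draw_from_ui(0.004, 0.004, 0.004, "logit", n_draws = 20, seed = 1)
  rr <- draw_from_ui(2.4, 2.4, 2.4, "log", n_draws = 20, seed = 2)
  deaths <- draw_from_ui(5000, 5000, 5000, "log", n_draws = 20, seed = 3)
  out <- propagate_draws(
    list(p = prev, rr = rr, d = deaths),
    function(x) attributable_stratum(compute_paf(x$p, x$rr), x$d))
  expect_true(all(out == compute_paf(0.004, 2.4) * 5000))
  expect_error(propagate_draws(list(a = prev, b = matrix(1, 1, 5)), identity),
               "mismatched draw counts")
})

test_that("RR draws around the null give mean PAF consistent with the log-normal bias", {
  withr::with_seed(31, {
    p <- 0.003; sd <- 0.05; n <- 2e4
    rr <- exp(rnorm(n, 0, sd))
    paf <- compute_paf(p, rr, warn_negative = FALSE)
    bias <- p * (exp(sd^2 / 2) - 1)           # E[RR] - 1 scaled by P
    mc_se <- sd(paf) / sqrt(n)
    expect_lt(abs(mean(paf)), bias + 4 * mc_se)
    expect_lt(abs(mean(paf)), 0.05 * p)       # negligible against P itself
  })
})

test_that("stochastically larger RR inputs give stochastically larger PAF draws", {
  lo <- draw_from_ui(2, 1.5, 2.7, "log", n_draws = 4000, seed = 8)
  hi <- draw_from_ui(3, 2.2, 4.1, "log", n_draws = 4000, seed = 8)
  paf_lo <- sort(compute_paf(0.01, lo))
  paf_hi <- sort(compute_paf(0.01, hi))
  # compare matched quantiles across the whole distribution
  expect_true(all(paf_hi >= paf_lo))
})

test_that("round trip draw -> summarise recovers value and interval", {
  d <- draw_from_ui(0.32, 0.27, 0.37, "logit", n_draws = 1e5, seed = 12)
  s <- summarise_draws(d)
  expect_equal(s$mean, 0.32, tolerance = 0.01)
  expect_equal(s$lower, 0.27, tolerance = 0.01)
  expect_equal(s$upper, 0.37, tolerance = 0.01)
})

test_that("Monte-Carlo error of summaries shrinks with the draw count", {
  s1 <- summarise_draws(draw_from_ui(100, 80, 125, "log", 1000, seed = 2))
  s2 <- summarise_draws(draw_from_ui(100, 80, 125, "log", 16000, seed = 2))
  # both agree with the construction within MC error scaling ~ 1/sqrt(n)
  expect_equal(s1$lower, 80, tolerance = 0.05)
  expect_equal(s2$lower, 80, tolerance = 0.0125)
  expect_equal(s1$upper, 125, tolerance = 0.05)
  expect_equal(s2$upper, 125, tolerance = 0.0125)
})

test_that("stratum-level intervals cover the truth at the nominal rate", {
  # classical coverage experiment for the draw construction itself: observe
  # a logit-scale quantity with sampling noise of the width its interval
  # describes, rebuild the interval from the observation, check it covers
  # the truth ~95% of the time
  p_true <- 0.0032
  sd_t <- (qlogis(0.0037) - qlogis(0.0027)) / (2 * qnorm(0.975))
  obs_all <- withr::with_seed(606, plogis(qlogis(p_true) +
                                            rnorm(400, 0, sd_t)))
  covered <- vapply(1:400, function(r) {
    obs <- obs_all[r]
    d <- draw_from_ui(obs, obs * 0.0027 / 0.0032, obs * 0.0037 / 0.0032,
                      "logit", n_draws = 1000, seed = 7000 + r)
    s <- summarise_draws(d)
    s$lower <= p_true && p_true <= s$upper
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("child seeds are deterministic, label-sensitive and in range", {
  expect_identical(child_seed(1, "prevalence"), child_seed(1, "prevalence"))
  expect_false(child_seed(1, "prevalence") == child_seed(1, "deaths:ihd"))
  expect_false(child_seed(1, "x") == child_seed(2, "x"))
  seeds <- vapply(1:200, function(i) child_seed(i, "q"), integer(1))
  expect_true(all(seeds > 0 & seeds < 2^31))
})
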