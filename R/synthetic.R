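# Synthetic worlds with known ground truth: study-level effect estimates,
# an age-declining prevalence curve for a rare exposure, age-increasing
# death/YLL envelopes and population counts, all mutually consistent so the
# full pipeline can be tested end-to-end without any external data.

#' Define a synthetic scenario with known ground truth
#'
#' Builds the complete ground truth of a synthetic world: per-outcome true
#' relative risks (with sex contrasts and a linear age trend on the log
#' scale), an exposure prevalence curve declining with age and scaled so
#' the population-weighted all-age prevalence hits `prevalence_all_age`
#' exactly, death and YLL envelopes rising with age, and population counts.
#' From these it derives — by the same attributable-burden arithmetic the
#' pipeline uses — the true stratum PAFs, attributable burden, and the
#' explained/unexplained decomposition, which are stored for oracle
#' comparisons.
#'
#' The defaults are calibrated to the published global operating point for
#' schizophrenia in 2019: pooled both-sex RRs of 2.36 (IHD, with a
#' female/male contrast of 2.73/2.04), 1.86 (stroke) and 4.08 (diabetes,
#' contrast 4.84/3.43), an all-cause RR of 2.89, RRs declining with age,
#' all-age prevalence 0.32%, and envelope totals of the order of the 2019
#' global burden (9.1M IHD, 6.5M stroke, 1.55M diabetes and 56.5M all-cause
#' deaths).
#'
#' @param age_start,age_open First age band lower bound and the lower bound
#'   of the terminal open band (defaults 15 and 85).
#' @param outcomes Named list of outcome parameter lists with elements
#'   `rr` (both-sex RR at the centring age), `sex_log_rr` (log female/male
#'   RR contrast), `age_slope` (per-year log-RR trend), `deaths_total`,
#'   `ylls_total`, `male_share_deaths`, and optionally `case_log_rr`,
#'   `pop_type_log_rr` (study-covariate effects, default 0).
#' @param all_cause Same structure for all-cause mortality.
#' @param prevalence_all_age Population-weighted all-age exposure
#'   prevalence (fraction; default 0.0032).
#' @param prevalence_decline Per-year exponential decline of prevalence
#'   with age (default 0.02, roughly halving over 35 years — the
#'   post-peak attrition of a rare disorder with marked excess mortality).
#' @param population_total Total population across strata (default 5.4e9,
#'   the global 15+ scale).
#' @param population_decline Per-year exponential decline of population
#'   with age (default 0.025).
#' @param death_age_growth,yll_age_growth Per-year exponential growth of
#'   the death / YLL envelopes with age (defaults 0.08 and 0.04).
#' @param tau2_study,tau2_estimate True between-study and within-study
#'   between-estimate variances of generated log effects (defaults 0.05,
#'   0.01).
#' @param age_centre Centring age for the log-RR trend (default 50; the
#'   study generator balances its age assignments around this value).
#' @param ui_rel Relative half-widths of the uncertainty intervals written
#'   on generated tables (defaults: prevalence 10%, deaths/YLLs 5%,
#'   population 2%).
#' @param rr_log_se Log-scale standard error attached to generated
#'   stratum-RR tables (default 0.05).
#' @return An object of class `"scenario_truth"`; see Details for the main
#'   elements: `strata` (the stratum grid with population and prevalence),
#'   `outcomes` / `all_cause` (per-outcome truth: `rr`, `paf`, envelopes,
#'   attributable burden and totals) and `summary` (all-age prevalence,
#'   explained/unexplained burden, percent explained).
#' @export
scenario_truth <- function(
    age_start = 15, age_open = 85,
    outcomes = list(
      ihd = list(rr = 2.36, sex_log_rr = log(2.73 / 2.04), age_slope = -0.02,
                 deaths_total = 9.1e6, ylls_total = 1.77e8,
                 male_share_deaths = 0.55),
      stroke = list(rr = 1.86, sex_log_rr = 0, age_slope = -0.02,
                    deaths_total = 6.55e6, ylls_total = 1.26e8,
                    male_share_deaths = 0.52),
      diabetes = list(rr = 4.08, sex_log_rr = log(4.84 / 3.43),
                      age_slope = -0.02,
                      deaths_total = 1.55e6, ylls_total = 3.4e7,
                      male_share_deaths = 0.48)),
    all_cause = list(rr = 2.89, sex_log_rr = 0, age_slope = -0.02,
                     deaths_total = 5.65e7, ylls_total = 1.67e9,
                     male_share_deaths = 0.54),
    prevalence_all_age = 0.0032, prevalence_decline = 0.02,
    population_total = 5.4e9, population_decline = 0.025,
    death_age_growth = 0.08, yll_age_growth = 0.04,
    tau2_study = 0.05, tau2_estimate = 0.01,
    age_centre = 50,
    ui_rel = list(prevalence = 0.10, deaths = 0.05, ylls = 0.05,
                  population = 0.02),
    rr_log_se = 0.05) {

  bands <- parse_age_group(default_age_bands(age_start, age_open))
  grid <- data.frame(sex = rep(SEXES, each = nrow(bands)),
                     bands[rep(seq_len(nrow(bands)), 2), ],
                     row.names = NULL)
  grid$age_mid <- age_midpoint(grid$age_lower, grid$age_upper)
  grid$sex_female <- as.numeric(grid$sex == "female")

  # population: equal sexes, exponential decline with age
  wpop <- exp(-population_decline * (grid$age_mid - age_start))
  grid$population <- population_total * wpop / sum(wpop)

  # prevalence: exponential age decline, scaled so the population-weighted
  # all-age prevalence equals the target exactly
  shape <- exp(-prevalence_decline * (grid$age_mid - age_start))
  scale <- prevalence_all_age /
    (sum(shape * grid$population) / sum(grid$population))
  grid$prevalence <- scale * shape
  if (any(grid$prevalence >= 1))
    stop_input("prevalence curve leaves [0, 1); lower prevalence_all_age or the decline")

  fill_defaults <- function(o) {
    o$case_log_rr <- o$case_log_rr %||% 0
    o$pop_type_log_rr <- o$pop_type_log_rr %||% 0
    o
  }
  outcomes <- lapply(outcomes, fill_defaults)
  all_cause <- fill_defaults(all_cause)

  envelope <- function(total, growth, male_share) {
    w <- grid$population * exp(growth * (grid$age_mid - age_start))
    sex_share <- ifelse(grid$sex == "male", male_share, 1 - male_share)
    # normalise age pattern within each sex, then split the total by sex
    v <- numeric(nrow(grid))
    for (s in SEXES) {
      i <- grid$sex == s
      v[i] <- total * sex_share[i][1] * w[i] / sum(w[i])
    }
    v
  }

  truth_outcome <- function(o) {
    lp <- log(o$rr) + o$sex_log_rr * (grid$sex_female - 0.5) +
      o$age_slope * (grid$age_mid - age_centre)
    rr <- exp(lp)
    deaths <- envelope(o$deaths_total, death_age_growth, o$male_share_deaths)
    ylls <- envelope(o$ylls_total, yll_age_growth, o$male_share_deaths)
    paf <- compute_paf(grid$prevalence, rr, warn_negative = FALSE)
    list(params = o, rr = rr, paf = paf,
         deaths = deaths, ylls = ylls,
         attrib_deaths = paf * deaths, attrib_ylls = paf * ylls,
         totals = list(
           deaths = sum(deaths), ylls = sum(ylls),
           attrib_deaths = sum(paf * deaths),
           attrib_ylls = sum(paf * ylls),
           prop_deaths = sum(paf * deaths) / sum(deaths),
           prop_ylls = sum(paf * ylls) / sum(ylls)))
  }

  oc <- lapply(outcomes, truth_outcome)
  ac <- truth_outcome(all_cause)

  # consistency: the all-cause envelope must dominate the summed
  # outcome-specific envelopes in every stratum
  sum_deaths <- Reduce(`+`, lapply(oc, `[[`, "deaths"))
  sum_ylls <- Reduce(`+`, lapply(oc, `[[`, "ylls"))
  if (any(sum_deaths > ac$deaths) || any(sum_ylls > ac$ylls))
    stop_input("outcome envelopes exceed the all-cause envelope in some strata")

  explained_deaths <- sum(vapply(oc, function(o) o$totals$attrib_deaths, 1))
  explained_ylls <- sum(vapply(oc, function(o) o$totals$attrib_ylls, 1))
  summary <- list(
    all_age_prevalence = prevalence_all_age,
    explained_deaths = explained_deaths,
    explained_ylls = explained_ylls,
    all_cause_attrib_deaths = ac$totals$attrib_deaths,
    all_cause_attrib_ylls = ac$totals$attrib_ylls,
    unexplained_deaths = ac$totals$attrib_deaths - explained_deaths,
    unexplained_ylls = ac$totals$attrib_ylls - explained_ylls,
    percent_explained_deaths = explained_deaths / ac$totals$attrib_deaths,
    percent_explained_ylls = explained_ylls / ac$totals$attrib_ylls)

  structure(list(
    params = list(age_start = age_start, age_open = age_open,
                  prevalence_all_age = prevalence_all_age,
                  prevalence_decline = prevalence_decline,
                  population_total = population_total,
                  population_decline = population_decline,
                  death_age_growth = death_age_growth,
                  yll_age_growth = yll_age_growth,
                  tau2_study = tau2_study, tau2_estimate = tau2_estimate,
                  age_centre = age_centre, ui_rel = ui_rel,
                  rr_log_se = rr_log_se),
    strata = grid, outcomes = oc, all_cause = ac, summary = summary),
    class = "scenario_truth")
}

#' The published-operating-point scenario
#'
#' [scenario_truth()] with its defaults: the synthetic world calibrated to
#' the published global 2019 operating point (pooled RRs 2.36 / 1.86 /
#' 4.08, all-cause RR 2.89, all-age prevalence 0.32%, envelope totals on
#' the global scale).
#'
#' @param ... Overrides passed to [scenario_truth()].
#' @return A `"scenario_truth"` object.
#' @export
paper_like_scenario <- function(...) scenario_truth(...)

# balanced study-design grids used by the generator: age ranges whose
# midpoints (30, 50, 70) average to the 50-year centring age when cycled
STUDY_AGE_RANGES <- list(c(20, 39), c(40, 59), c(60, 79))

#' Generate study-level effect estimates from a scenario truth
#'
#' Per study draws a study-level random intercept `u ~ N(0, tau2_study)`;
#' per estimate a nested effect `v ~ N(0, tau2_estimate)` and a sampling
#' error `N(0, se^2)` with `se` uniform in `se_range`. The observed log
#' effect is `x'beta + u + v + error`, with the linear predictor taken
#' from the scenario's true outcome parameters. Covariates are assigned on
#' balanced deterministic grids: sexes alternate within a study
#' (percent female 0.5 when a study contributes a single estimate), age
#' ranges cycle over midpoints 30/50/70 years, and the binary study
#' covariates alternate across studies.
#'
#' @param truth A [scenario_truth()].
#' @param outcome Outcome name in `truth` (or `"all_cause"`).
#' @param n_studies Number of studies (>= 1).
#' @param estimates_per_study Estimates contributed by each study.
#' @param se_range Interval for the uniform sampling-error SE draw.
#' @param seed Integer seed; equal seeds give identical tables.
#' @return A study-estimate data frame in the same schema as
#'   [read_study_table()] output (plus `value`, `ci_lower`, `ci_upper` so
#'   it can be written to and re-read from the raw-effect CSV contract).
#' @export
generate_studies <- function(truth, outcome = "ihd", n_studies = 30,
                             estimates_per_study = 2,
                             se_range = c(0.1, 0.3), seed = 1) {
  stopifnot(inherits(truth, "scenario_truth"))
  if (n_studies < 1 || estimates_per_study < 1)
    stop_input("n_studies and estimates_per_study must be >= 1")
  if (length(se_range) != 2 || any(!is.finite(se_range)) ||
      any(se_range <= 0) || se_range[2] < se_range[1])
    stop_input("se_range must be a positive interval c(lower, upper)")
  o <- if (outcome == "all_cause") truth$all_cause$params
       else truth$outcomes[[outcome]]$params
  if (is.null(o)) stop_input("unknown outcome '%s'", outcome)

  n <- n_studies * estimates_per_study
  study <- rep(seq_len(n_studies), each = estimates_per_study)
  # sex cycles with period 2 and age with period 3 over the flat estimate
  # index, so the two assignments stay linearly independent (and their
  # interaction identifiable) for any estimates-per-study count
  pf <- if (estimates_per_study == 1) rep(0.5, n)
        else rep_len(c(0, 1), n)
  rng <- STUDY_AGE_RANGES[((seq_len(n) - 1) %% 3) + 1]
  age_lower <- vapply(rng, `[`, 1, 1)
  age_upper <- vapply(rng, `[`, 1, 2)
  age_mid <- age_midpoint(age_lower, age_upper)
  case_def <- (study - 1) %% 2
  pop_type <- ((study - 1) %/% 2) %% 2

  lp <- log(o$rr) + o$sex_log_rr * (pf - 0.5) +
    o$age_slope * (age_mid - truth$params$age_centre) +
    o$case_log_rr * case_def + o$pop_type_log_rr * pop_type

  tau2s <- truth$params$tau2_study
  tau2e <- truth$params$tau2_estimate
  dat <- with_seed(seed, {
    u <- stats::rnorm(n_studies, 0, sqrt(tau2s))[study]
    v <- stats::rnorm(n, 0, sqrt(tau2e))
    se <- stats::runif(n, se_range[1], se_range[2])
    err <- stats::rnorm(n, 0, se)
    data.frame(log_value = lp + u + v + err, se = se)
  })
  z <- z_quantile(0.95)
  out <- data.frame(
    study_id = sprintf("S%03d", study),
    outcome = outcome,
    measure = "RR",
    value = exp(dat$log_value),
    ci_lower = exp(dat$log_value - z * dat$se),
    ci_upper = exp(dat$log_value + z * dat$se),
    se = dat$se,
    log_value = dat$log_value,
    measure_origin = "RR",
    percent_female = pf,
    age_lower = age_lower,
    age_upper = age_upper,
    age_mid = age_mid,
    case_definition = case_def,
    population_type = pop_type,
    stringsAsFactors = FALSE)
  out
}

# observation-noise draw matching the distributional form draw_from_ui
# assumes for the quantity, so coverage experiments are self-consistent
observe_around <- function(value, rel, transform) {
  tr <- transform_spec(transform)
  lo <- value * (1 - rel)
  hi <- value * (1 + rel)
  ok <- tr$domain(value) & tr$domain(lo) & tr$domain(hi)
  sdv <- ifelse(ok, (tr$f(hi) - tr$f(lo)) / (2 * z_quantile(0.95)), 0)
  obs <- tr$inv(stats::rnorm(length(value), ifelse(ok, tr$f(value), 0), sdv))
  ifelse(ok, obs, value)
}

#' Generate the world tables of a scenario
#'
#' Emits the full input bundle of the burden pipeline as validated stratum
#' tables: exposure prevalence, population, and per-outcome (plus
#' all-cause) death and YLL envelopes, each with 95% uncertainty intervals
#' of the configured relative width; per-outcome stratum relative-risk
#' tables carry the truth's RRs with log-scale intervals. By default the
#' table values equal the ground truth exactly, so the pipeline run with
#' uncertainty disabled must reproduce the stored true attributable burden
#' to floating-point accuracy. With `observation_noise = TRUE` every value
#' is instead drawn from the distribution its uncertainty interval
#' describes (logit-normal for prevalence and death proportions,
#' log-normal for YLLs, population and RRs), which is the sampling model
#' needed for interval-coverage experiments.
#'
#' @param truth A [scenario_truth()].
#' @param seed Integer seed (used only when `observation_noise = TRUE`).
#' @param observation_noise Draw observed values around the truth instead
#'   of copying it.
#' @return A list of class `"cra_world"`: `prevalence` and `population`
#'   stratum tables, `outcomes` (per outcome: `deaths`, `ylls`, `rr`),
#'   `all_cause` (same shape), and `meta`.
#' @export
generate_world <- function(truth, seed = 1, observation_noise = FALSE) {
  stopifnot(inherits(truth, "scenario_truth"))
  g <- truth$strata
  rel <- truth$params$ui_rel
  zs <- z_quantile(0.95)

  make_tab <- function(value, rel_width, quantity, transform, scale = NULL) {
    # `scale` maps a count to the (0,1) proportion its logit draws live on
    v <- value
    if (observation_noise) {
      if (!is.null(scale)) {
        v <- observe_around(value / scale, rel_width, transform) * scale
      } else {
        v <- observe_around(value, rel_width, transform)
      }
    }
    stratum_table(data.frame(sex = g$sex, age_group = g$age_group,
                             value = v,
                             ui_lower = v * (1 - rel_width),
                             ui_upper = v * (1 + rel_width)),
                  quantity)
  }
  make_rr <- function(rr) {
    se <- truth$params$rr_log_se
    v <- rr
    if (observation_noise) v <- exp(stats::rnorm(length(rr), log(rr), se))
    data.frame(sex = g$sex, age_group = g$age_group, value = v,
               ui_lower = exp(log(v) - zs * se),
               ui_upper = exp(log(v) + zs * se))
  }

  build <- function() {
    prevalence <- make_tab(g$prevalence, rel$prevalence, "prevalence", "logit")
    population <- make_tab(g$population, rel$population, "population", "log")
    one <- function(o) list(
      deaths = make_tab(o$deaths, rel$deaths, "deaths", "logit",
                        scale = g$population),
      ylls = make_tab(o$ylls, rel$ylls, "ylls", "log"),
      rr = make_rr(o$rr))
    list(prevalence = prevalence, population = population,
         outcomes = lapply(truth$outcomes, one),
         all_cause = one(truth$all_cause))
  }
  world <- if (observation_noise) with_seed(seed, build()) else build()
  world$meta <- list(seed = seed, observation_noise = observation_noise)
  class(world) <- "cra_world"
  world
}

#' Write / read a world bundle in the canonical table dialect
#'
#' Writes every stratum table of a world to `dir` (prevalence.csv,
#' population.csv, and `deaths_<outcome>.csv` / `ylls_<outcome>.csv` /
#' `rr_<outcome>.csv` including `all_cause`), so a generated world is
#' indistinguishable from user-supplied input files. `read_world()` is the
#' inverse.
#'
#' @param world A `"cra_world"` list from [generate_world()].
#' @param dir Output directory (created if absent).
#' @return `dir` (write) or a `"cra_world"` list (read), invisibly/visibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stratum_table(world$prevalence, file.path(dir, "prevalence.csv"))
  write_stratum_table(world$population, file.path(dir, "population.csv"))
  all_oc <- c(world$outcomes, list(all_cause = world$all_cause))
  for (oc in names(all_oc)) {
    write_stratum_table(all_oc[[oc]]$deaths,
                        file.path(dir, paste0("deaths_", oc, ".csv")))
    write_stratum_table(all_oc[[oc]]$ylls,
                        file.path(dir, paste0("ylls_", oc, ".csv")))
    rr <- all_oc[[oc]]$rr
    utils::write.csv(data.frame(sex = rr$sex, age_group = rr$age_group,
                                value = rr$value, lower = rr$ui_lower,
                                upper = rr$ui_upper),
                     file.path(dir, paste0("rr_", oc, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  if (!dir.exists(dir)) stop_input("world directory not found: %s", dir)
  files <- list.files(dir)
  ocs <- sub("^deaths_(.*)\\.csv$", "\\1",
             grep("^deaths_.*\\.csv$", files, value = TRUE))
  ocs <- setdiff(ocs, "all_cause")
  if (!length(ocs)) stop_input("no outcome envelope files in %s", dir)
  read_rr <- function(path) {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    data.frame(sex = tolower(raw$sex),
               age_group = normalise_age_label(raw$age_group),
               value = raw$value, ui_lower = raw$lower, ui_upper = raw$upper)
  }
  one <- function(oc) list(
    deaths = read_stratum_table(file.path(dir, paste0("deaths_", oc, ".csv")),
                                "deaths"),
    ylls = read_stratum_table(file.path(dir, paste0("ylls_", oc, ".csv")),
                              "ylls"),
    rr = read_rr(file.path(dir, paste0("rr_", oc, ".csv"))))
  world <- list(
    prevalence = read_stratum_table(file.path(dir, "prevalence.csv"),
                                    "prevalence"),
    population = read_stratum_table(file.path(dir, "population.csv"),
                                    "population"),
    outcomes = stats::setNames(lapply(ocs, one), ocs),
    all_cause = one("all_cause"),
    meta = list(dir = dir))
  class(world) <- "cra_world"
  world
}
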