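---
title: "Methods: comparative risk assessment of fatal burden attributable to schizophrenia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative risk assessment of fatal burden attributable to schizophrenia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craburden)
```

## The estimation problem

Schizophrenia carries a two- to four-fold excess mortality from ischaemic
heart disease (IHD), stroke and diabetes, but because death certification
assigns a single underlying cause, none of that burden is visible under
the disorder itself. The comparative risk assessment (CRA) framework
recovers it by treating schizophrenia as a risk factor: with exposure
prevalence $P$ and relative risk $RR$ in a stratum, the population
attributable fraction

$$\mathrm{PAF} = \frac{P\,(RR - 1)}{P\,(RR - 1) + 1}$$

is the share of the stratum's burden that would not occur under the
counterfactual of no exposure (the theoretical minimum risk exposure
level). Multiplying stratum PAFs by the death and years-of-life-lost
(YLL) envelopes and summing gives attributable burden; dividing by total
burden gives the attributable proportion. Subtracting the summed
outcome-specific attributable burden from the all-cause attributable
burden gives the *unexplained* burden — the part of the excess mortality
the modelled outcomes do not account for.

## Pooling relative risks

Study-level mortality ratios arrive as RRs, standardised mortality
ratios or hazard ratios with 95% confidence intervals. With exposure
prevalence near 0.3% the three measures are numerically near-identical,
so the default conversion policy is the rare-outcome identity, recorded
per row in a provenance tag (`convert_to_rr()`); the policy argument is
the hook for published conversion formulas when their auxiliary inputs
exist. Standard errors are recovered from the interval bounds on the log
scale, $(\log u - \log \ell) / (2 z_{0.975})$, with $z$ always computed
from the normal quantile so non-default confidence levels stay correct.
Rows with neither an interval nor an explicit standard error are dropped
with a logged reason.

Pooling per health outcome uses a three-level random-effects
meta-regression with estimates nested within studies,

$$y_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + u_i + v_{ij} +
\varepsilon_{ij}, \qquad u_i \sim N(0, \tau^2_{study}),\;
v_{ij} \sim N(0, \tau^2_{estimate}),\;
\varepsilon_{ij} \sim N(0, se_{ij}^2),$$

fitted by REML with `metafor::rma.mv` (a configuration switch drops the
estimate-level component). Moderators are percent female (a continuous
fraction, not a binary), the age-range midpoint, their interaction, case
definition (schizophrenia only vs including schizoaffective disorder)
and population type (inpatient and outpatient vs inpatient only).
Continuous moderators are centred at their estimate-weighted means, so
the exponentiated intercept is the pooled both-sex RR at the mean age.
Age midpoints use $(\ell + u + 1)/2$ for closed integer-year bands and
$\ell + 5$ for the open terminal band.

Moderator selection is backward elimination on AIC. Comparisons across
fixed-effect structures are made on maximum-likelihood fits — AIC is not
valid across fixed effects under REML — and the final model is refit by
REML. We count $\mathrm{AIC} = -2\log L + 2(p + q)$ with $p$ fixed
coefficients and $q$ estimated variance components. The interaction is
never retained without both mains, and mains are not candidates while
the interaction is present. Exact ties (within $10^{-8}$) drop the
covariate listed later in (interaction, case definition, population
type, percent female, age), preserving main effects longest. Covariates
can be forced in — the intended use is retaining population type as a
bias control for an outcome observed in a single inpatient-only study.
Because AIC keeps a null covariate whenever its likelihood-ratio
statistic exceeds 2 (probability about 0.16 each under the null),
elimination from five null covariates ends at the intercept-only model
in only roughly a third of replicates while pruning most covariates on
average; the test suite asserts that derived behaviour rather than a
higher figure.

Single-estimate inputs are special-cased (the pooled value is the
estimate, variance components fixed at zero) because the likelihood
cannot identify heterogeneity from one observation. Optimiser failures
at boundary solutions are retried across a small ladder (nlminb,
Nelder–Mead, BFGS, then a perturbed start) before an error carrying all
optimiser messages is raised.

## Attribution and uncertainty

Inputs are age–sex stratum tables (two sexes, contiguous 5-year bands
from a configurable start — default 15–19 … 80–84 plus 85+, the adult
mortality focus — validated for completeness, contiguity and domain).
Prevalence is a fraction; a percent-scaled file must be declared
explicitly (`percent = TRUE`), never auto-detected. Counts aggregate by
summation, prevalences by population-weighted mean; asking for a
weighted mean of a count table is an error.

RRs enter per stratum either from the fitted model (sex coded 0/1 at
prediction even though pooling used a continuous fraction) or from an RR
table with log-scale intervals. RRs below 1 yield negative PAFs, which
are flagged and never clipped. Strata with zero envelope contribute zero
attributable burden regardless of PAF.

Uncertainty propagation follows the draw-based GBD convention: 1000
independent samples of every input, normal on a transformed scale with
standard deviation $(\,t(u) - t(\ell)\,)/(2 \times 1.959964)$, the
deterministic chain applied per draw, and summaries taken as the mean
and the 2.5th/97.5th quantiles (linear interpolation between order
statistics, R's type 7). The published description of this step as a
Markov chain Monte Carlo simulation is implemented as independent
parametric draws: sampling from the input distributions requires no
chain, and no chain structure is described. Prevalence is drawn on the
logit scale; death counts are drawn as logit-normal *proportions of the
stratum population* (the only reading under which deaths are bounded in
(0, 1)) and rescaled to counts; YLLs and population are drawn on the log
scale. Values sitting on a transform boundary (0, or 1 for logit)
degenerate to constants with a warning. RR uncertainty uses draws of the
coefficient vector from its estimated covariance (`rr_draw_mode =
"joint"`; a marginal mode ignores covariances — the joint default is
correct whenever the covariance is available). Input draws are mutually
independent, matching the source-by-source sampling described for the
published analysis.

Every quantity draws under a child seed derived deterministically from
the run's root seed and the quantity's label, so adding or removing an
outcome never perturbs the other quantities' draws, and any single
quantity can be re-drawn in isolation. The per-draw identity
`all_cause = explained + unexplained` is exact; draws in which explained
exceeds all-cause are kept as negative unexplained values and counted.
Because point estimates are means of draws, additive identities on
*rounded* published point values can be off by one in the last digit;
the per-draw identity is the tested contract.

## The synthetic generator

`scenario_truth()` builds a world with fully known ground truth:
log-linear RR age trends with sex contrasts, an exponentially
age-declining prevalence curve scaled so the population-weighted all-age
prevalence hits its target *exactly*, exponentially age-increasing death
and YLL envelopes split by sex, and population counts. The stored truth
(stratum PAFs, attributable burden, decomposition) is recomputed with
the same arithmetic the pipeline uses, so a pipeline run with
uncertainty disabled must reproduce it to floating-point accuracy — the
strongest end-to-end oracle the suite has.

The default calibration is the published 2019 global operating point:
pooled both-sex RRs 2.36 (IHD), 1.86 (stroke), 4.08 (diabetes) and 2.89
(all-cause); sex contrasts from the published sex-specific RRs
(2.73/2.04 for IHD, 4.84/3.43 for diabetes — their geometric means
recover the pooled values exactly); an RR age decline of 0.02/yr;
all-age prevalence 0.32%; envelope totals at the 2019 global scale
(9.1M, 6.55M, 1.55M and 56.5M deaths; YLL totals back-computed from the
published attributable proportions). Where the calibration surface is
silent the defaults are one-time realism choices: prevalence declining
at 0.02/yr (roughly halving over 35 years, the post-peak attrition of a
rare disorder with marked excess mortality), population declining at
0.025/yr, death envelopes growing at 0.08/yr and YLLs at 0.04/yr of
age, between-study variance 0.05 and within-study between-estimate
variance 0.01 on the log scale, and interval half-widths of ±10%
(prevalence), ±5% (envelopes) and ±2% (population). Study covariates are
assigned on balanced deterministic grids (sex cycling with period 2 and
age ranges with midpoints 30/50/70 cycling with period 3 over the flat
estimate index) so the assignments stay linearly independent and the
empirical centring matches the truth's centring age of 50.

What the generator does *not* emulate: location heterogeneity, secular
trends, correlated moderators, non-normal effect distributions,
reporting and publication bias, and the Bayesian machinery behind real
prevalence estimates. Passing tests therefore certify the estimation
machinery — they do not certify that the published numbers are
recoverable from real data, which would require the deposited study
tables and burden extracts.

## Problem sizes and numerical choices

The suite's simulation experiments use sizes chosen to make Monte-Carlo
error small relative to the asserted tolerances: coefficient recovery
over 200 replicates of 30 studies × 2 estimates (asserted within 2
Monte-Carlo standard errors); REML optimality against a 20×20
variance-component grid on instances of 8 estimates, checked with a
hand-written restricted likelihood independent of the fitting engine;
elimination behaviour over 40 (null) and 30 (strong-age) replicates;
interval calibration over 500 replicates at 1000 draws; and the
calibration surface at 120 studies × 2 estimates, where the pooled RRs
must sit within three standard errors of their targets.

One calibration finding is worth stating plainly: stratum-level draw
intervals are well calibrated (≈95% coverage in the suite's
experiments), but the interval for an *aggregated total* is mildly
anti-conservative (≈92–93% at the default interval widths). The reason
is structural: back-transformed log/logit-normal noise has mean above
median, so both the observed inputs and the draws shift the total's
location upward by a fixed relative amount while summation shrinks the
total's spread, concentrating misses below the interval. This property
is inherent to draw-based uncertainty propagation on transformed scales
— it travels with the method, not with this implementation.

Other numerical choices: convergence tolerance is metafor's default on
the REML objective; quantiles are type 7 throughout; the degenerate
zero-width interval produces exact constants (no transform round-trip
error); CSV writers emit 17 significant digits so write-then-read is the
identity; and all randomness flows from explicit seeds through the
child-seed derivation, making every table and every run reproducible bit
for bit.
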