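---
title: "Modelling carbon-stock buildup in planted mangroves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling carbon-stock buildup in planted mangroves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangrovebuildup)
```

## The scientific problem

Planted mangrove stands of known age, scattered across the tropics, form a
space-for-time chronosequence: stands of different ages stand in for the
trajectory a single restoration site would follow. For each planted stand
we form the buildup ratio `R = C_planted / mean(C_intact)` against intact
reference stands in the same geomorphic setting, separately for
aboveground biomass (AGB), belowground biomass (BGB) and soil carbon to
1 m. Working on ratios removes the enormous between-site variation in
absolute stocks (an estuary in Borneo and a lagoon in Madagascar share no
baseline) and leaves a dimensionless quantity with a natural
interpretation: `R = 1` means parity with intact forest.

## The model

The ratio is modelled as a logistic function of stand age,

$$ R(\mathrm{age}) = \frac{R_{\max}}{1 + \exp[-\beta_0 - \beta_1
   \ln(\mathrm{age})]} $$

with multiplicative lognormal noise, i.e. a normal likelihood on the log
ratio:

$$ \ln R_i \sim \mathcal{N}\!\left(\ln R_{\max} - \ln\{1 +
   \exp[-\beta_0 - \beta_1 \ln(\mathrm{age}_i)]\},\; \sigma\right). $$

`Rmax` is the asymptotic planted-to-intact ratio and is *not* constrained
to 1: some planted stands plateau below intact stocks, others overshoot.
`beta0` locates the curve on the log-age axis (it is the log-odds of
`R/Rmax` at age 1 year), `beta1` is the slope per unit `ln(age)`, and
`sigma` is the residual sd of the log ratio. All logarithms are natural;
the closed-form inversion

$$ \mathrm{age}(R) = \exp\!\left[\frac{\ln\frac{R}{R_{\max}-R} -
   \beta_0}{\beta_1}\right] $$

(`age_at_ratio()`) depends on that convention and returns `Inf` when the
target ratio is at or above `Rmax` — the stand never gets there.

### Priors

`ln Rmax ~ N(0, 2.5)`, `beta0 ~ N(0, 5)`, `beta1 ~ N(0, 2.5)` and a flat
Jeffreys prior on `ln sigma`. These are weakly informative on the scales
that matter for logistic curves: the `beta0` prior puts 95% of its mass on
log-odds between −10 and 10 (i.e. essentially the full curve range at age
1), and the `beta1` prior allows a unit change of log-age to move the
log-odds by up to ±5. `prior_interval_mass()` computes such masses
analytically; `fit_posterior()` with zero observations samples the prior,
and the test suite checks that those draws reproduce the analytic normal
quantiles. The improper `ln sigma` prior is realized as uniform on
`ln sigma ∈ [−10, 10]` so the density is proper for sampling; the box is
five orders of magnitude wider than any plausible residual sd, and the
prior-recovery test confirms the bounds are only ever active in the
no-data case.

### Age zero

Chronosequences legitimately contain observations at the time of planting
(`age = 0`), where `ln(age)` is undefined. The likelihood floors ages at
`age_floor_yr` (default 0.25 yr, i.e. the first growing season) before
taking logs; the floor is a `fit_config()` field, and the synthetic
generator applies the same floor so generation and inference agree. The
curve itself uses the analytic age→0 limit (0 for rising curves, `Rmax`
for falling ones) wherever a "time of planting" value is needed, e.g. in
`net_gain()`.

## Posterior computation

The posterior over `(ln Rmax, beta0, beta1, ln sigma)` — the unconstrained
parameterization matching the priors' natural scales — is sampled by an
in-package Metropolis scheme:

* a Laplace approximation (BFGS mode + regularized inverse Hessian) seeds
  the proposal covariance and overdispersed chain starts;
* iterations alternate an **independence proposal** (multivariate t, 4 df,
  centered at the mode with inflated covariance), which mixes almost
  ideally on this near-Gaussian 4-parameter posterior, with an **adaptive
  random-walk step** whose scale and covariance adapt during warmup only
  (Haario-style, on the post-transient half of the warmup history), which
  keeps the kernel correct where the Laplace approximation is poor;
* after warmup the kernel is frozen, so retained draws target the exact
  posterior.

Defaults are 4 chains × (1500 warmup + 2500 retained) draws. Convergence
is gated, not advisory: `fit_posterior()` raises a
`buildup_convergence_error` carrying the full diagnostics table whenever
any split-R̂ exceeds 1.01 or any effective sample size falls below 100
(rank-plain split-R̂ and Geyer-truncated ESS, computed in-package). All
randomness flows from the single integer seed in `fit_config()`; identical
seeds give identical draws.

An importance-sampling estimator written independently in the test
helpers (Gaussian proposal at the mode, self-contained density code)
cross-checks the posterior means, so the sampler is never validated
against itself.

## Pairing rules and their defaults

* **Local match**: all intact stands of the same geomorphic class within
  10 km are used, and the ratio divides by their mean stock
  (compartment-wise; missing values ignored, never zero-filled).
* **Remote fallback**: the paper trail for remote references is a climatic
  plus geomorphic class. No standard climatic classification is fixed by
  the data, so the package bins absolute latitude into 10° bands — the
  simplest reproducible proxy — and exposes the band width in
  `pairing_config()`. Intact stands sharing a `site_id` form one cluster;
  distance is measured to the cluster centroid (a flag switches to
  nearest-stand distance), capped at 400 km, which covers the few-hundred-
  kilometre range over which remote references are credible.
* **Unmatched stands** are dropped with a logged reason — an expected
  outcome, not an error.
* **Stratum floor**: strata (compartment × composition group, plus the
  pooled `all` group per compartment) with fewer than 30 observations or
  6 distinct studies are excluded. These defaults reproduce the canonical
  borderline case of a 27-observation, 5-study stratum being dropped, and
  both floors are configurable.

## Soil-stock harmonization

Soil stocks are comparable only at a common depth. `compute_soil_stock()`
integrates bulk density × thickness × %C over core layers (grams per cm²,
converted at 1 g cm⁻² = 100 Mg ha⁻¹), and `scale_to_1m()` rescales
sampled stocks to 1 m by either:

* `depth_proportional` — `stock / depth × 100`, assuming uniform stock
  density; used both to extrapolate shallow cores and interpolate deep
  ones, and the package default;
* `bd_carbon` — reconstruct `BD × %C × 100` from core-average bulk
  density and carbon content. The published description of this method is
  terse; the implementation assumes the product over a 100-cm column and
  treats the method as secondary. When layers are available the averages
  are depth-weighted (the physically consistent choice); otherwise plain
  summary values are accepted.

`evaluate_scaling_methods()` regresses observed 1-m stocks (y) on each
method's predictions (x) — that axis order is deliberate and documented —
and recommends the higher-R² method. Stocks already sampled at exactly
100 cm pass through untouched.

## The synthetic generator

`simulate_dataset()` draws site clusters on a jittered 1° grid (so
clusters sit >50 km apart while stands within a site stay within ~2 km —
cleanly inside the local-match radius), assigns each site one geomorphic
class with weights matching the observed prevalence of deltas and
estuaries, gives intact stands lognormal stocks around the literature
means for intact mangroves (AGB 99.05, BGB 48.91, soil 276.65 MgC ha⁻¹;
between-site log-sd 0.5, within-site 0.1), and generates planted stocks
from the logistic curve with multiplicative lognormal noise. Ages are
log-uniform on [0.5, 40] yr with a 5% point mass at age 0 to exercise the
age-floor rule. Default generating curves: biomass compartments with
asymptotes 0.71–0.73 and residual sd 0.3; soil nearly flat around 0.75
with larger noise (sd 0.45), echoing the empirical pattern of a fast
early soil-ratio rise followed by four decades of constancy.

What the generator does **not** emulate: spatial autocorrelation beyond
site clustering, intertidal-position effects, compartment-wise missing
data patterns, study-level biases (allometric-equation families,
loss-on-ignition conversions), or tidal carbon export. Passing tests
therefore demonstrate correctness of the pipeline and the inference under
the model's own assumptions — not robustness to every failure mode of
field compilations.

## Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to make the statistics
sharp at desk scale: single-fit parameter recovery uses n = 250 ratio
observations (posterior means land within 3 posterior sds of truth);
interval calibration uses 10 seeded replicates of the full
simulate→pair→fit loop, scoring the average coverage of 90% credible
intervals over the four parameters against its binomial band
[0.82, 0.98]; prior-mass Monte-Carlo checks use 10⁶ draws. The curve/age
round-trip is enforced to 10⁻⁹ relative error, the soil-stock integrator
is compared against a 1-mm brute-force gram accounting, and
`log1p(exp(x))` is evaluated with the standard threshold decomposition so
log-odds of ±745 neither overflow nor lose the likelihood.

## Known limitations

* One stratum is fit at a time; there is no hierarchical pooling across
  genera, no spatial random effects, and no measurement-error model for
  the intact reference mean.
* The climatic-band proxy is a stand-in for a real climatic
  classification; with strongly zonal data a coarser or finer band width
  may change which remote matches exist (it is a config field for that
  reason).
* "Slope probability" is reported as the one-sided posterior tail
  `min(P(beta1 ≤ 0), P(beta1 ≥ 0))` together with `P(beta1 > 0)`;
  two-sided analogues can be derived from the draws directly.
* The ratio at age 0 for a rising curve is exactly 0 by the limit rule,
  so net gains from planting implicitly assume no pre-existing stock in
  the modelled compartment; for soil, where planting sites retain large
  stocks, the nearly flat fitted curve — not the limit rule — carries the
  science.
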