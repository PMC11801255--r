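# mangrovebuildup

Chronosequence meta-analysis of blue-carbon stocks in planted (restored or
afforested) mangrove stands, relative to intact reference forests.

Mangrove planting is the dominant restoration strategy for one of the most
carbon-dense ecosystems on Earth, yet the timeline over which planted
stands rebuild the carbon stocks of intact forests is contested. The
natural observable is the **buildup ratio**

> *R* = C_planted / mean(C_intact)

computed per ecosystem compartment (aboveground biomass, belowground
biomass, soil to 1 m) between each planted stand and intact stands of the
same geomorphic setting nearby. This package implements the full analysis
pipeline around that quantity:

1. **Stand data** — CSV schemas, validation and the meta-analysis
   exclusion criteria (missing location/composition/age, unreplicated
   single-core data) for stand-level carbon records.
2. **Preprocessing** — soil C stocks from layered core profiles
   (BD × depth × %C, summed over layers) and rescaling of all soil stocks
   to the 1-m reference depth, with an observed-vs-predicted regression
   comparison of the two standard scaling methods.
3. **Pairing** — haversine-distance matching of planted stands to intact
   references (local ≤ 10 km within geomorphic class; remote fallback to
   the nearest same-class, same-climatic-band site cluster), ratio
   construction, and stratification by compartment × composition with
   minimum-data exclusion rules.
4. **Growth model** — a Bayesian nonlinear logistic model of the log
   ratio,

   ```
   R(age) = Rmax / (1 + exp(-beta0 - beta1 * ln(age)))
   ln R_i ~ Normal( ln Rmax - ln(1 + exp(-beta0 - beta1 ln age_i)), sigma )
   ln Rmax ~ N(0, 2.5),  beta0 ~ N(0, 5),  beta1 ~ N(0, 2.5),  ln sigma ∝ 1
   ```

   fit by an in-package adaptive MCMC sampler with split-R̂/ESS gates, plus
   posterior-derived recovery curves, the closed-form age at which a
   target ratio is reached, slope probabilities, Bayesian R² and
   prior-interval masses.
5. **Prediction** — posterior ratios multiplied against intact-stock value
   sets to give absolute predicted stocks by age and net carbon gains
   between planting and a horizon.
6. **Synthetic data** — a seeded generator producing paired
   planted/intact datasets from the model itself, so the entire pipeline
   and parameter-recovery experiments run without any external data.

## Worked example

```r
library(mangrovebuildup)

sim <- simulate_dataset(synthetic_config(seed = 42))   # 240 planted, 80 intact
cfg <- pairing_config(min_stratum_obs = 20, min_stratum_studies = 2)
obs <- build_ratios(sim$stands, cfg)
st  <- build_strata(obs, cfg)

fit <- fit_posterior(st$strata[["bgb:all"]],
                     cfg = fit_config(seed = 42), stratum = "bgb:all")
fit
#> <buildup_fit> stratum=bgb:all  n_obs=240  draws=10000 (4 chains)
#>   Rmax   0.722 [0.651, 0.803]
#>   beta0  -2.601 [-2.742, -2.460]
#>   beta1  1.432 [1.359, 1.510]
#>   sigma  0.299 [0.273, 0.327]
#>   max split-Rhat 1.0025, min ESS 2341, accept 0.45

summarize_curve(fit, ages = c(5, 10, 20, 40))
#>   age_yr      mean     lower     upper
#> 1      5 0.3071437 0.2899972 0.3246899
#> 2     10 0.4803239 0.4569007 0.5048419
#> 3     20 0.6079113 0.5678388 0.6495630
#> 4     40 0.6748038 0.6183782 0.7342543

g <- net_gain(fit, intact_stock_set("bgb", 48.91), t_end = 40)
sprintf("net BGB gain after 40 yr: %.1f [%.1f, %.1f] MgC/ha",
        g$mean, g$lower, g$upper)
#> "net BGB gain after 40 yr: 33.0 [30.2, 35.9] MgC/ha"
```

The generating curve behind this synthetic dataset has asymptote
`Rmax = 0.73` and residual sd `sigma = 0.3`; the fitted posterior brackets
both, the curve summary shows belowground biomass reaching ~60% of intact
stocks by year 20, and the net-gain line converts the ratio increase into
absolute carbon per hectare against a literature-scale intact stock of
48.91 MgC ha⁻¹.

The same stages run end to end, with file handoffs and a JSON manifest,
through `run_pipeline()`:

```r
run_pipeline(list(seed = 42, out_dir = "out",
                  strata = "bgb:all",
                  pairing = list(min_stratum_obs = 20,
                                 min_stratum_studies = 2)))
```

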