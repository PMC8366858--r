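# scoterhab

Bayesian habitat-use modelling for wintering sea ducks surveyed by aerial
strip transects, built around the Black Scoter (*Melanitta americana*) on
the South Atlantic Bight. The package takes a survey from raw geometry to
inference: it grids transect lines into 1,000 m × 550 m cells and sums
flock sightings into per-cell, per-year counts; derives oceanographic and
weather covariates (bathymetry, ocean floor slope, Euclidean distance to
shore, latitude, inverse-distance-weighted buoy wind speed and wave period,
and the yearly North Atlantic Oscillation index); and fits a hierarchical
negative binomial regression with Bayesian indicator-variable selection to
identify which covariates drive relative abundance.

## The model

Counts in cell *i* and year *t* follow a negative binomial,

y_it ~ NegBinom(p_it, r),   p_it = r / (r + mu_it),

where `r` is the overdispersion parameter (variance mu + mu²/r, so small
`r` means many empty cells and rare, very large flocks) and the mean is
log-linear in 13 standardized terms:

log mu_it = b0 + b1·NAO_t + b2·bathy_i + b3·bathy_i² + b4·slope_i
          + b5·dist_i + b6·dist_i² + b7·wind_it + b8·wind_it²
          + b9·wave_it + b10·wave_it² + b11·lat_i
          + b12·NAO_t·bathy_i + b13·NAO_t·dist_i.

Each coefficient is a spike-and-slab product `b_k = gamma_adj_k * delta_k`
with `gamma_k ~ Bernoulli(0.5)` inclusion indicators, a shared slab
`delta_k ~ Normal(0, sigma)`, `sigma ~ InvGamma(1, 1)`, and
`r ~ Uniform(0, 10)`. Strong heredity is enforced by multiplying
indicators: a quadratic or interaction term can only enter when all of its
parent linear terms are in (e.g. `gamma_adj[NAO×bathy] =
gamma[NAO]·gamma[bathy]·gamma[NAO×bathy]`). Sampling is by a compiled
Metropolis-within-Gibbs sampler in the Kuo–Mallick parameterization;
zero-inflated Poisson and zero-inflated negative binomial variants are
available for model comparison. Fit is checked with posterior-predictive
Bayesian p-values based on the Freeman–Tukey discrepancy
`T = sum (sqrt(y) − sqrt(mu))²`, and convergence with split-chain
Gelman–Rubin R-hat.

A synthetic-data generator (`scoter_scenario()`, `simulate_survey()`)
emulates the survey design — east-west transects every 5 nm (2.5 nm in the
intensive final year), the 14.8 km / 16-m-isobath length rule, a shelf-like
bathymetry with shoal noise, 20 wind and 9 wave buoys, yearly NAO values —
so the whole pipeline runs and is validated without any external data.

## Worked example

Generate a survey under the `"survey_like"` scenario (active effects on
bathymetry +0.4, slope −0.8, wave period +0.6, NAO +0.3 and NAO×bathymetry
+0.5; `r = 0.1`) and run the full pipeline:

```r
library(scoterhab)
sc  <- preset_scenario("survey_like", seed = 1)
sim <- simulate_survey(sc, "scoter-sim")
out <- run_pipeline("scoter-sim",
                    config = mcmc_config(n_chains = 2, n_adapt = 500,
                                         n_burn = 500, n_iter = 1000,
                                         seed = 2))
print(out)
```

```
Grid-cell count summary
  cells sampled : 2285
  occupied      : 590 (25.8%)
  mean          : 3.61
  quantiles     : 2.5% = 0, 50% = 0, 97.5% = 31
  max           : 535

Spike-and-slab NB count regression
  2285 observations, 2 chains x 1000 retained draws (seed 2)
  prior convention: bugs-precision; converged: TRUE (max R-hat 1.015)
  inclusion probabilities:
        nao       bathy      bathy2       slope        dist       dist2
      1.000       1.000       0.076       1.000       0.038       0.004
       wind       wind2        wave       wave2    latitude nao_x_bathy
      0.235       0.019       1.000       0.124       0.110       1.000
 nao_x_dist
      0.005

Posterior-predictive check (Freeman-Tukey), 2000 draws
  Bayesian p-value: 0.351
```

The five generating terms are recovered with inclusion probability 1.0
while every null term stays near or below the 0.5 prior; the Bayesian
p-value of 0.35 shows no misfit signal (values below 0.1 or above 0.9
would flag one). Sign summaries and response curves follow the same fit:

```r
prob_positive(out$fit)[c("bathy", "slope", "wave", "nao_x_bathy")]
#>       bathy       slope        wave nao_x_bathy
#>           1           0           1           1

head(subset(out$curves, nao_level == -3.9), 4)
#>   nao_level bathymetry_m mean lower upper
#> 1      -3.9        -48.2 3.92 0.925 10.89
#> 2      -3.9        -46.8 3.71 0.934  9.94
#> 3      -3.9        -45.4 3.51 0.934  9.08
#> 4      -3.9        -44.0 3.33 0.934  8.37
```

`out$curves` holds the predicted relative abundance (expected scoters per
1,000 m × 550 m cell) along the observed bathymetry range at the low
(−3.9), moderate (−1.4) and high (2.8) NAO phases; with a positive
NAO×bathymetry coefficient the depth preference reverses between phases.
`prob_positive()` is `P(beta > 0)` over all retained draws, with spike
draws at exactly zero counted as non-positive.

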