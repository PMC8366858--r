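---
title: "Modelling wintering Black Scoter habitat use from strip-transect surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wintering Black Scoter habitat use from strip-transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoterhab)
```

## The scientific problem

Black Scoters winter on open water along the southeastern U.S. coast in a
distribution that is mostly empty space punctuated by enormous rafts:
across a multi-year aerial survey most 1,000 m segments hold no birds at
all while a handful hold thousands. The question the package addresses is
which oceanographic and weather conditions shape that distribution — and it
does so with a model whose parts (counting design, covariate construction,
variable selection, goodness of fit, prediction) are each testable in
isolation.

## From flight lines to counts

Aerial strip transects run east–west, spaced 5 nautical miles apart (2.5 nm
in an intensive final year restricted to the southern half of the block).
`segment_transect()` divides each flown line into half-open along-track
intervals of 1,000 m. The strip half-width is 275 m: the observers' 250 m
band plus a 25 m GPS-error allowance on each side, so a cell is
1,000 m × 550 m. Three conventions are pinned for reproducibility:

* **Trailing remainders** are kept as flagged partial cells by default
  (dropping them would systematically discard the offshore end of each
  transect and bias covariates such as distance to shore); exclusion or
  merging are config switches.
* **Boundary ties** use the half-open rule: a sighting exactly on an
  interior cell boundary belongs to the later cell. Sightings whose
  unclamped along-track position falls before the start or at/after the
  end of the line, or farther than 275 m from it, are dropped and counted,
  never silently lost — total birds assigned plus drops equals total
  recorded.
* **Geometry** is computed on a local equirectangular projection about the
  southwest corner of the transect bounding box (meter-true at the study
  latitude; the block is ~2° across, where this projection's length
  distortion is far below one cell). The generator and the pipeline share
  the same origin rule so both produce identical planar geometry.

Count summaries report type-1 (lower-nearest order statistic) quantiles so
that all quantiles of integer counts are integers.

## Covariates

Seven linear covariates enter the model: yearly NAO index, bathymetry (m,
elevation convention — sea floor negative), ocean floor slope (degrees),
distance to shore (km), latitude, and survey-window averages of wind speed
(m/s) and wave period (s).

* **Slope** differences neighboring raster cells: central differences over
  the four rook neighbors (one-sided at edges), gradient magnitude
  `g = sqrt(gx² + gy²)`, slope `atan(g)` in degrees. This is the simplest
  reading of "difference of the values between neighboring cells" and is
  checkable against an analytic plane; Horn's 8-neighbor stencil would
  change values by well under the covariate's standard deviation.
* **Distance to shore** is the planar Euclidean minimum from the cell
  center to any shoreline segment.
* **Wind and wave fields** are interpolated from daily buoy records by
  inverse distance weighting with power 2 (the conventional default;
  configurable), distances in km on the projected plane, then averaged
  over the survey dates of each year. IDW is exact at buoy sites and
  bounded by the observed extremes.
* **NAO** uses the February monthly value of each survey year (the surveys
  fly in February); a multi-month mean is a config switch.
* **Standardization** is `(x − mean)/sd` with the sample sd (n − 1) over
  all modeled cell-years. The constants — and the observed ranges, used to
  warn about extrapolation — are stored with the design matrix and reused
  verbatim for prediction. Quadratic and interaction columns are plain
  products of standardized linear columns and are *not* re-standardized:
  the selection prior treats them as derived terms of the linear predictor,
  and re-scaling them would break the heredity interpretation.
* **Collinearity screening** computes absolute pairwise Pearson
  correlations and warns (never errors) when any pair reaches 0.6, the
  conventional admission threshold for this model family.

The design matrix has 14 fixed, named columns (intercept + 13 terms); its
quadratic/interaction columns reconstruct exactly from the linear ones,
which the tests assert as a checksum.

## The selection model and its sampler

Counts are negative binomial with `p = r/(r + mu)` and continuous
overdispersion `r ~ Uniform(0, 10)`; the mean is log-linear in the 13
terms. Each coefficient is `beta_k = gamma_adj_k · delta_k` (Kuo–Mallick):
`gamma_k ~ Bernoulli(0.5)`, `delta_k ~ Normal(0, sigma)` with the slab
variance `sigma ~ InvGamma(1, 1)` shared across terms, and strong heredity
applied by multiplying indicators, so
`gamma_adj[NAO×bathy] = gamma[NAO]·gamma[bathy]·gamma[NAO×bathy]`.

**Prior convention.** Gibbs-sampler dialects disagree on whether
`Normal(0, 0.01)` names a precision or a moment. The default
(`prior_spec(convention = "bugs-precision")`) reads the intercept prior as
precision 0.01 (sd 10), the vague choice a JAGS-style analysis would make;
`"moment"` reads it as variance 0.01. The slab is parameterized by its
variance in both conventions so the inverse-gamma update stays conjugate,
and every fit records which convention it used.

**Updates.** One compiled Metropolis-within-Gibbs sweep updates:

1. the intercept by a random-walk MH step;
2. each included `delta_k` by random-walk MH; each *excluded* `delta_k` is
   refreshed from its slab prior — its full conditional, which is what
   lets the corresponding `gamma_k` re-enter later;
3. each `gamma_k` from its Bernoulli full conditional, with the likelihood
   evaluated under heredity recomputation for the term and all terms it
   parents;
4. `sigma` from its conjugate inverse-gamma full conditional given all 13
   deltas;
5. `r` by random-walk MH on `log r` (with Jacobian), rejecting outside
   (0, 10); and, for zero-inflated variants, the inflation weight `w` on
   the logit scale under its Uniform(0, 1) prior.

Proposal scales adapt toward 20–50% acceptance during a discarded
adaptation phase and are frozen afterward, preserving detailed balance in
the retained draws. The linear predictor is maintained incrementally with
a periodic exact recomputation to cap round-off drift. All randomness runs
through R's RNG, so a fit is bit-reproducible from its seed. Multiple
chains start from dispersed initial values; split-chain Gelman–Rubin
R-hat is computed for the intercept, `sigma`, `r` and every coefficient
with inclusion above 0.2, and non-convergence (R-hat ≥ 1.1) is flagged in
the fit object and as a warning — never silently ignored.

The sampler's correctness is cross-checked three independent ways in the
tests: the exhaustive heredity oracle; a no-data run (all indicators fixed
off) whose `sigma` chain must reproduce the analytic InvGamma(1, 1)
marginal; and, with all indicators fixed on, agreement of all posterior
means with an independent JAGS implementation of the same hierarchical
model.

**Zero-inflated variants.** The comparison models mix a structural zero
(weight `w ~ Uniform(0, 1)`, intercept-only — the minimal structure when
nothing more is known about the inflation process) with a Poisson or
negative binomial count component on the same log-linear mean.

## Goodness of fit and summaries

The posterior-predictive check computes, per retained draw, the
Freeman–Tukey discrepancy of the observed data `T(y, mu)` and of a
replicate simulated from the fitted family at that draw, and reports
`p = mean(T_rep >= T_obs)` — ties counted, the conservative convention.
Values outside (0.1, 0.9) flag lack of fit. The replicate stream is seeded
independently of the sampler. Because the check uses fitted parameters,
its p-values concentrate near 0.5 under the true model rather than being
uniform, which is why a well-specified fit lands comfortably inside the
flag bounds.

`inclusion_probabilities()` is the posterior mean of the
heredity-adjusted indicators. `prob_positive()` is the fraction of *all*
retained draws with `beta_k > 0`: spike draws (term excluded, `beta_k`
exactly zero) count as non-positive, which makes the statistic a joint
statement about selection and sign; the slab-conditional version is
available alongside.

"Relative abundance" predictions are posterior expected counts per
1,000 m × 550 m cell — the model's native unit, with no density rescaling
— summarized by the posterior mean and the equal-tailed 95% interval.
Interaction-response curves fix every other covariate at its survey mean
(standardized zero), sweep bathymetry on its raw scale, and condition on
NAO at the low/moderate/high phase values observed across the survey
winters (−3.9, −1.4, 2.8); requests outside the fitted covariate range
warn about extrapolation rather than refusing.

## What the synthetic generator emulates — and what it does not

`scoter_scenario()` reproduces the *design* of the study: transect spacing
and the length rule (the longer of 14.8 km or the distance to the 16-m
isobath; fixed ~18.5 nm lines in the intensive year), cell geometry, 20
wind and 9 wave buoys, one NAO value per year, and counts drawn from the
model itself.

The seascape is built from three parts chosen so that the generated
covariates satisfy the same admission screen the analysis applies to real
data (all pairwise |r| < 0.6):

* an **exponential-plateau depth profile** — depth deepens near shore at a
  latitude-varying rate and flattens toward an alongshore-varying shelf
  plateau. A constant-gradient profile is available for analytic slope
  checks, but it makes depth an almost deterministic function of distance
  to shore once transects are truncated at the 16-m isobath; the plateau
  (which the long intensive-year transects sample, where depth no longer
  tracks distance) plus shoal noise is what keeps that correlation near
  0.5, as on a real shelf;
* **shoal/bank relief** as box-blurred white noise (raw sd 36 m, one blur
  pass, effective sd ≈ 9 m at ~4 km correlation length) — this also gives
  the slope covariate realistic spatial texture;
* **weather fields** with a weak latitudinal mean gradient, per-buoy,
  per-year centered site anomalies (winter storm patterns differ between
  years; centering keeps the regional mean in the base level so the
  four-point year design cannot alias the NAO covariate), and daily AR(1)
  noise truncated to physical ranges.

The `"survey_like"` preset activates bathymetry (+0.4), slope (−0.8), wave
period (+0.6), NAO (+0.3, required by heredity) and NAO×bathymetry (+0.5),
with `r = 0.1` and NAO fixed at the observed phase values. Two generator
choices deserve their rationale spelled out:

* **`r = 0.1`.** Overdispersion estimated from real wintering-scoter
  surveys is near 0.005 — so extreme that the
  Fisher information per cell is roughly `r` itself, and the synthetic
  survey's ~2,300 cells would carry almost no information about the
  coefficients: parameter recovery would fail *by design*, not by defect.
  `r = 0.1` preserves the phenotype that matters (≈75% empty cells, median
  0, single cells in the hundreds-to-thousands) while making the scenario
  informative enough that recovery is a meaningful test of the sampler.
  This is a deliberate scaled-down study condition, fixed before any
  acceptance measurement and not revisited.
* **Flock sizes arise purely from NB overdispersion**, not an explicit
  flocking/movement process. That reproduces the zero-heavy, huge-max
  count marginal but none of the spatial autocorrelation a raft of real
  birds induces among neighboring cells.

Consequently, passing the recovery and calibration suites demonstrates
that the *method* is implemented correctly under its own assumptions; it
does not demonstrate robustness to detection error, spatial dependence,
observer effects, or covariate measurement error, none of which the
generator emulates (and the first of which the survey itself cannot
resolve).

## Problem sizes and numerical choices

The validation suites run at sizes chosen to make Monte Carlo noise small
relative to the tolerances they assert: recovery fits use the full
~2,300-cell scenario with 3 chains × 2,000 retained draws (single chains
of 1,000 for the 20 replicate coverage runs); calibration of the
posterior-predictive check uses 20 replicates of n = 500; the conjugate
`sigma` check uses 4,000 post-burn draws against the analytic quantiles.
Degenerate inputs are rejected loudly (zero-length transects, empty
shorelines, all-missing buoy days, zero-variance covariates, non-finite
linear predictors name the offending object or row). Ties in sighting
assignment and in the p-value are pinned by convention, not left to
floating-point accident.

## Known limitations

* The model is not conditioned on presence and has no detection submodel,
  spatial random effects, or temporal autocorrelation; inference about
  habitat is inference about *observed* relative abundance.
* The NAO enters as a single February value per year; with four survey
  years, any year-level covariate rests on four support points.
* The equirectangular projection is adequate for blocks a few degrees
  across at mid-latitudes, not for basin-scale work.
* The Kuo–Mallick sampler mixes well here because covariates are
  standardized and effects are moderate; with extreme collinearity or very
  vague slabs, indicator chains can stick — the R-hat flags, inclusion
  monitors, and the JAGS cross-check in the test suite are the guardrails.
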