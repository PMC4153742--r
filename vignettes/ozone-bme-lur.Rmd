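---
title: "Spatiotemporal ozone estimation with kriging, LUR and BME-LUR"
author: "bmelur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal ozone estimation with kriging, LUR and BME-LUR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmelur)
```

## The problem

Daily 8-hr summer ozone over a large region is monitored by a sparse
network (a few dozen stations over hundreds of kilometres).  Health
studies need exposure estimates at unmonitored locations, which calls
for spatiotemporal interpolation.  This package implements and compares
three estimators on that problem:

1. **LUR** — a linear-spline mixed-effects land-use regression of ozone
   on temperature, precipitation, day of year, year, road density and
   rescaled latitude, with a per-station random intercept;
2. **space-time kriging** — simple kriging of detrended, normal-scored
   station data under a nested space-time covariance ("hard" data
   only);
3. **BME-LUR** — a Bayesian Maximum Entropy estimator that augments the
   hard data with Gaussian "soft" data: at each grid cell, the LUR
   fixed-effect prediction with its prediction-error SD.

With Gaussian soft data the BME posterior is available in closed form
and coincides with kriging under heteroscedastic data noise, so the
production solver is analytic; a Gauss–Hermite quadrature oracle
(`bme_numeric_oracle()`) evaluates the BME integral numerically and is
used in the test suite to verify the analytic path to ~1e-6.

## The LUR model

For station \(s\) and day \(t\),
\[
O_3(s,t) = \beta_0 + \beta_1 T^{\le 18}(s,t) + \beta_2 T^{>18}(s,t)
 + \beta_3 P(s,t) + \beta_4 D(t) + \beta_5 Y(t)
 + \beta_6 R^{\le 15}(s) + \beta_7 R^{>15}(s)
 + \beta_8 L^{\le 50}(s) + \beta_9 L^{>50}(s) + u_s + \varepsilon,
\]
where the superscripted pairs are single-knot linear splines
(temperature knot 18 °C, road-density knot 15 km/πkm², latitude knot
50 km), \(D\) is the day of year minus 121, \(Y\) the year minus 1990,
\(u_s \sim N(0, \sigma_u^2)\) a station random intercept and
\(\varepsilon\) the residual.  Fitting is by REML through `lme4` (ML by
option); both are deterministic.  The packaged reference coefficient
set for the Quebec network (1990–2009) has \(\sigma_u = 2.464\) ppb and
\(\sigma_\varepsilon = 8.904\) ppb:

```{r}
d <- default_lur_coefficients()
round(unclass(d$coefficients), 3)
```

The effect size of a covariate over its observed range follows the
spline decomposition
\(\beta_{low}(knot - v_{min}) + \beta_{up}(v_{max} - knot)\); for
example `effect_size(d$coefficients, "road_density", 0, 25.4)` returns
`r round(effect_size(d$coefficients, "road_density", 0, 25.4), 3)` ppb.
Effect sizes are reported signed; the day-of-year coefficient is
negative, so its effect size is negative and its magnitude is the
quantity usually quoted.

**Soft-data error.**  The prediction-error variance of the fixed-effect
prediction is the quadratic form \(x^\top \Sigma_\beta x + \sigma_u^2\)
(`predict_error_sd()`), not the sum of squared coefficient standard
errors: the latter ignores coefficient covariances and the magnitude of
the covariates and cannot produce realistic error magnitudes.  The
literal summed-SE variant is available behind `method = "literal"` for
comparison.  Whether \(\sigma_\varepsilon^2\) belongs in the soft error
is genuinely ambiguous: excluding it treats the soft datum as knowledge
of the *local fixed-effect mean*; including it treats the soft datum as
knowledge of the *station-day concentration*.  The package default
excludes it (`include_residual = FALSE`); the cross-validation studies
below include it, because in the synthetic world the observed value the
estimator is judged against contains the residual, and a soft record
claiming a ~2.5 ppb error for a quantity it predicts to ~9 ppb is badly
over-confident and misleads the estimator.

## Detrending and normal scores

Estimation runs in a transformed space.  A Gaussian-kernel space-time
trend (`fit_trend()`; bandwidths interpreted as kernel SDs, defaults
25 km and 2 days) is subtracted, and the residuals are mapped to
standard-normal scores by the rank-based n-score transform
(`nscore_fit()`, piecewise-linear with linear tail extrapolation).
Estimates are back-transformed in reverse order: denormalize, then
retrend.  Both steps are exact inverses on their fitting sets.  The
pipeline order (detrend first, then n-score) is a fixed, documented
choice; the opposite order is available via
`fit_transform(order = "nscore_first")`.

Soft records are transformed by pushing their means through the same
path and rescaling their SDs by the local slope of the n-score map
(first-order delta method), which preserves the Gaussian soft form the
analytic solver requires.  Posterior SDs are back-transformed by the
delta method at the estimate; a Monte-Carlo back-transform is available
as the reference (`back_transform(method = "mc")`).

Note that at a data point the kernel trend is dominated by the point's
own kernel weight, so "residuals" at data points are essentially
short-time innovations.  This matters for cross-validation (below).

## The nested space-time covariance

Transformed residuals are modelled by
\[
C(r, \tau) = w_1\, e^{-3r/a_{s1}}\, e^{-3\tau/a_{t1}}
 + w_2\, e^{-3r/a_{s2}} \cos(\pi \tau / a_{t2}),
\]
the sum of a dominant long-range (100 km), short-memory (2 days)
exponential component (\(w_1 = 0.9\)) and a local (12.5 km) component
(\(w_2 = 0.1\)) whose cosine factor represents the weekly urban ozone
cycle.  Exponentials use the practical-range convention
\(e^{-3r/a}\).  The cosine interpretation — first sign change at
\(a_{t2} = 3\) days, period 6 days — is a documented reading of
"3-day cosinusoidal"; the component is not by itself a valid
covariance in continuous space-time, so validity of the nested sum is
enforced empirically by positive-semi-definiteness checks with a small
jitter ladder wherever a covariance matrix is factorized.

`empirical_covariance()` estimates binned space-time covariances from
all data pairs (default spatial bin edges 0, 5, 12.5, 25, 50, 100,
200 km; integer temporal lags 0–14 days, straddling the model's
ranges); `fit_covariance()` fits the five free parameters by weighted
least squares (weights = pair counts) with the sill fixed at the
zero-lag estimate, using a fixed deterministic grid of starting values
with L-BFGS-B on log-range scales.

## Estimation

`estimate_points()` runs, per target point: neighbor selection (ranked
by model covariance, deterministic distance-then-id tie-breaks; default
at most 10 hard and 10 soft neighbors within 500 km and 60 days — the
neighborhood sizes are conventional, configurable choices), the
analytic Gaussian solve (jitter ladder 1e-10 to 1e-6 before a point is
declared a numerical failure), and the back-transform.  Failures are
first-class outcomes carried in a status column, never silent.  An
optional conflict check (`soft_conflict_sd`) flags points whose hard
neighbors all lie far outside the soft envelope — the estimation
failure mode observed in practice when observed values far exceed what
the soft data support — as failures rather than crashing.

## Cross-validation protocol

`loso_cv()` implements leave-one-station-out cross-validation with a
temporal exclusion: for an evaluation station-day \((s_0, t_0)\), all
hard data of \(s_0\) in the window \((t_0 - 365, t_0]\) are withheld;
kriging and BME-LUR then estimate the withheld observation, and the LUR
column carries the fixed-effect prediction.  Soft data are not rebuilt
per fold (each station contributes only a few percent of the LUR fit).
The covariance model is likewise fold-invariant.

One subtlety deserves emphasis: the kernel trend must not be evaluated
at the withheld point using a fit that includes the withheld station —
the withheld observation would re-enter through its own kernel
self-weight and the own-station short-lag weights, leaking exactly the
temporal autocorrelation the protocol is designed to remove.  The
package therefore refits the trend and n-score map without the
evaluation station (once per station; data more than a few temporal
bandwidths away cannot influence the trend at the evaluation day, so
full-station exclusion is equivalent to windowed exclusion for the
transform).  An `audit_ok` flag on every record verifies that no
excluded datum entered a neighbor set.  Setting the window to 0
deliberately retains the evaluation point and must reproduce it exactly
— a leak-detection control used in the test suite.

Metrics (`cv_metrics()`): R² as the squared Pearson correlation (the
1 − SSE/SST variant by flag), RMSE, PCMSE
\(= 100\,( \mathrm{RMSE}_{ref} - \mathrm{RMSE}_{model}) /
\mathrm{RMSE}_{model}\) against the BME-LUR reference (this RMSE-ratio
form reproduces the published −23.0% worked example from the published
RMSEs, the MSE-ratio form does not; both are available), and Cohen's
kappa on exceedances of the 65-ppb 8-hr standard with a large-sample
CI.  Non-estimable points are excluded from metrics and tallied.

## The synthetic world

The generator emulates the study conditions of a sparse Quebec-like
summer network, not its geography.  Defaults: a 400 × 580 km planar
region, 30 stations with ~60% clustered toward the urban southwest
corner; road density from a right-skewed surface (exponential decay
from the urban center times lognormal noise, truncated to
[0, 25.4] km/πkm², station moments ≈ 6.4 ± 7 matching the observed
network); rescaled latitude \(y - \min y\) (0–583 km); temperature a
seasonal parabola (peak ≈ 22 °C mid-season) minus a 10 °C north–south
gradient plus shared day anomalies and station-day noise, clipped to
[−3.5, 33.9] °C; precipitation zero-inflated (~65% dry) gamma, clipped
to [0, 123.8] mm/day; seasons of 152 days separated by 365-day years.
Ozone is the LUR fixed mean (packaged coefficients) + station intercept
(SD 2.464 ppb) + a residual field with the nested covariance scaled to
SD 8.904 ppb, truncated at 0 ppb.  Because the nested model is a sum of
two *separable* components, the residual field is simulated exactly as
the sum of two independent Kronecker-factorized fields — factorizing
the station-by-station and day-by-day covariance factors separately —
which is exact for the full space-time covariance and far cheaper than
factorizing the joint matrix.

Grid covariates for soft data take each cell's meteorology from its
nearest station (as the study did with its closest weather monitor),
draw road density from the same road surface, and use the same latitude
origin (the southernmost station) as the station table; a cell
containing a monitor inherits the monitor's road density, since both
describe the same 1-km buffer.

What the generator does *not* emulate: real meteorology and
photochemistry, wind, covariate-correlated residuals (in the real world
part of the residual field is weather-driven and hence partially
predictable from covariates; here the residual is independent of the
covariates by construction), real geography, and instrument artifacts.
Passing tests therefore demonstrate correctness and calibration of the
estimators under the stated generative assumptions, not performance on
real data.

## Numerical and design choices

* **Parameter-recovery study conditions.**  Coefficient recovery for
  the LUR is assessed on data generated under the mixed model's own
  assumptions (an effectively uncorrelated residual field: nested model
  with sub-km, sub-day ranges).  REML standard errors assume
  independent residuals; under strongly space-time-correlated residuals
  their ±2 SE coverage is systematically below nominal, which is a
  property of the mixed model, not of the fitting code.  The correlated
  regime is exercised by the covariance-recovery and cross-validation
  studies instead.  Recovery is summarized as the fraction of
  coefficient × replicate pairs within ±2 SE (expected ≈ 95%).
* **Cross-validation study conditions.**  30 stations, two 60-day
  seasons, 80 evaluation station-days in the second season (the first
  season identifies the year term and gives the temporal exclusion
  something to exclude); soft data for the evaluation season only
  (mirroring soft data produced for the cross-validation reference
  year) on a 50-km grid *plus monitor-resolving cells*
  (`gen_grid_covariates(station_cells = TRUE)`: a 1-km operational grid
  always contains a cell sharing a monitor's road buffer, which a
  coarse desk-scale grid cannot represent otherwise); soft error
  including the residual variance (see above; measured calibrated,
  claimed ≈ actual ≈ 9.3 ppb); covariance refitted per replicate from
  the transformed residuals, since the generating ppb-scale model does
  not describe the detrended, normal-scored field; estimation
  neighborhoods of at most 10 hard and 3 soft records, the BME software
  family's conventional small soft neighborhood — soft records are
  locally redundant and their errors spatially correlated, which the
  diagonal-noise Gaussian soft formulation cannot represent, so dense
  soft neighborhoods are spuriously over-confident.  These sizes keep
  one replicate at a few seconds.
* **Degenerate inputs.**  Zero-noise data short-circuit `fit_lur()` to
  the exact OLS solution with zero variance components; kriging at a
  retained data point returns the observation with zero variance
  end-to-end; empty neighborhoods and singular systems produce status
  flags; empty soft tables warn.
* **Ties and determinism.**  Neighbor ties break by distance then id;
  n-score ties share averaged ranks; every stochastic function takes a
  seed and restores the caller's RNG state; covariance fitting uses a
  fixed multi-start grid.

## Known limitations

* The delta-method transform of soft SDs is first-order; for soft SDs
  large relative to the curvature scale of the n-score map it can
  misstate the transformed variance (the Monte-Carlo back-transform is
  exact in distribution and available for audit).
* Soft records are treated as carrying independent errors, as the
  Gaussian-soft BME formulation requires; spatially correlated soft
  errors (shared LUR fitting error, shared unresolved residual) make
  dense soft neighborhoods somewhat over-confident.
* The cosine covariance component is used as an empirical descriptor;
  its validity is enforced numerically, not analytically.
* R² of cross-validated estimates is a squared correlation and does not
  penalize calibration errors.
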