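---
title: "Modeling daily dew point with an IDW baseline and boosted residuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling daily dew point with an IDW baseline and boosted residuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`xisdew` estimates daily dew point at arbitrary points from a station
network, following the XGBoost--IDW synthesis (XIS) design: inverse-distance
weighting over the day's stations supplies a baseline estimate for every
station-day, and a gradient-boosted tree ensemble models the residual

$$\hat y(s, d) \;=\; \mathrm{IDW}_{-s}(d) \;+\; f_\theta\big(x(s, d)\big),$$

where $\mathrm{IDW}_{-s}(d)$ is the leave-self-out inverse-distance estimate
at station $s$ on day $d$ and $x(s,d)$ is an 18-slot predictor vector: the
IDW value itself, daily aggregates of hourly gridded reanalysis humidity and
temperature, two satellite column-water-vapor (CWV) values (one per
satellite), and 13 static land-use covariates. The residual learner corrects
the systematic part of what interpolation misses — terrain and land-use
effects, reanalysis bias — while the IDW anchor keeps the model honest where
predictors carry no signal. Predictions are point estimates; no per-prediction
uncertainty is produced.

Three daily dependent variables (DVs) are supported, and each gets its own
model:

* **mean humidity** — the time-weighted daily mean dew point;
* **T-min humidity** — the dew point recorded at the observation where the
  station's temperature reaches its daily minimum;
* **T-max humidity** — the same at the daily temperature maximum.

The extrema deliberately are *not* the day's extreme dew points: taking the
dew point that co-occurs with the temperature extremum guarantees that, say,
maximum temperature and T-max humidity describe genuinely simultaneous
conditions when combined into a heat index.

## From sub-daily records to station-days

A study day is a midnight-to-midnight interval at a fixed UTC−6 offset;
daylight saving is never applied, so day assignment depends only on the
instant. Timestamps must carry an explicit UTC offset and are rejected
otherwise.

Cleaning keeps a dew-point observation only when a finite temperature is part
of the same record, and drops dew points outside user-supplied record bounds
(defaults 210–310 K, suitable for synthetic work; supply climatological
record bounds for real data). Supersaturated records (dew point above
temperature) are counted in a diagnostic but never dropped — dew point is not
forced below temperature anywhere in the package.

The daily mean uses trapezoidal-interval time weights: each observation
carries half the gap to its temporal neighbors, and the first and last
observation additionally carry the gap to the day boundary, capped at
`boundary_cap_hours` (default 1 h). The cap keeps a lone early or late
reading from dominating the mean; with symmetric uniform spacing the weights
collapse to the arithmetic mean. Extremum ties are broken toward the earliest
observation so results are deterministic and order-independent. A station-day
is kept only if it has at least `min_obs` observations (default 4) spanning
at least `min_span_hours` (default 18 h); both are configurable because no
canonical completeness rule exists.

## The IDW baseline

Distances are great-circle on a 6371 km sphere. The estimate over the $k$
nearest in-radius neighbors is $\sum_i d_i^{-p} v_i / \sum_i d_i^{-p}$, with
$p = 2$ and $k = 8$ by default and no radius cap; none of these values is a
claim about any particular published configuration — they are conventional
defaults, recorded in model metadata for reproducibility. Stations within
`exact_hit_epsilon_km` (default 1 m) of the query are treated as coincident
and averaged, which keeps the estimate deterministic under reordering. For
training rows the target's own station is always excluded; a single-station
day therefore has a missing IDW feature, and such rows are retained (the
trees see the missingness; the residual target falls back to the
training-mean DV).

## Predictors

Hourly gridded humidity/temperature fields are reduced, per cell, to the
DV-analogous daily value: the simple average of the day's 24 hourly values
for the mean DV, or the value at the hour of the cell's temperature extremum
(earliest hour on ties) for the extrema. Gaps in the fine field — in real
products most common along coasts — are filled from the coarse field by
nearest-cell-center lookup, with a provenance mask recording the source of
every cell. CWV values are kept only where the QA bitmask's low three bits
differ from 3 (the cloudy-pixel code); Terra and Aqua stay separate features.

All grid lookups are nearest-cell-center (ties toward the lower index), not
bilinear: the daily rasters are per-cell products, and nearest-cell semantics
keep the fallback mask well defined. Gridded fields are carried in a plain
`grid_field` container serialized as long-format CSV, a deliberately
text-based format.

The 13 static covariates live in a named registry
(`default_feature_registry()`): longitude, latitude, elevation, distance from
water, population density, site isolation, two day-of-year harmonics, and
five further land-use style covariates (impervious fraction, canopy fraction,
nightlights, distance to urban center, slope). The registry is a snapshot in
every fitted model, and prediction refuses feature tables whose registry does
not match. Missing values (IDW, CWV) reach the tree learner as native
missings; the OLS baseline instead imputes per-feature training-fold medians,
since a linear model has no native missing-value route.

## Fitting and tuning

The ensemble is XGBoost with squared-error objective, subsampling and column
sampling fixed at 1, and a zero base score, so zero boosting rounds reduce
the model exactly to the IDW feature. Fits are deterministic given the seed.
Per-DV default hyperparameters are the tuned set

| DV   | nrounds | max_depth | eta | gamma | lambda | alpha |
|------|---------|-----------|-------|-------|--------|-------|
| min  | 500 | 9 | 0.078 | 0.38 | 360 | 0.57 |
| mean | 500 | 9 | 0.078 | 0.38 | 360 | 0.57 |
| max  | 500 | 9 | 0.051 | 0.37 | 120 | 0.28 |

These values were selected on national-scale archives with millions of rows;
their heavy L2 regularization underfits the few-thousand-row synthetic
scenarios this package ships, so `desk_scale_hyperparameters()` (600 rounds,
depth 4, eta 0.1, lambda 1) is provided and used for the desk-scale
model-comparison scenario.

Hyperparameter search draws candidates with a maximin Latin hypercube:
among `n_designs` random LHS draws (each stratifying every parameter into
$n$ equal-width bins), the design with the largest minimum pairwise distance
in the unit cube is kept. Candidates are ranked by RMSEZ: each region-year
column of the candidate-by-cell weighted-RMSE matrix is standardized to
z-scores across candidates — the sample-SD ($n-1$) convention, stated here
because either convention is defensible — and summarized by the per-candidate
mean and maximum. Standardization runs across candidates within cells (not
across cells within a candidate) because that is the reading that makes
candidates comparable for selection. Final selection is deliberately manual:
`tune_candidates()` emits the ranked table with fit times and both RMSEZ
summaries.

## Evaluation

Cross-validation is station-level: folds partition stations, not rows, so a
model never scores a station it trained on. Crucially, the IDW feature is
recomputed inside each fold — validation rows take their IDW estimate from
training-fold stations only, and training rows take leave-self-out estimates
within the training fold. Reusing the all-station IDW feature would leak the
held-out stations' observations through the baseline, which we consider the
only defensible reading of station-level CV.

Reported metrics are weighted RMSE, weighted SD of the observations, and
bias. The weighting scheme is explicit because no canonical definition
exists: the default is inverse-density (a station's weight is proportional to
$1/(1 + \text{neighbors within 50 km})$, normalized to mean 1), which keeps
dense metropolitan clusters from dominating domain-wide error; `uniform` is
available and every report names its scheme. Two conventional subsets are
provided: stations at least 12 km from every other station (evaluated to
check performance away from the network), and hot station-days with maximum
temperature at or above 92 °F (306.4833 K, evaluated unweighted).

`compare_baselines()` evaluates, under identical folds and weights, the IDW
feature alone, OLS on the full predictor vector, and the boosted model.
`attribution_summary()` computes exact tree SHAP values of the residual
ensemble, verifies per-row additivity (attributions plus base value equal the
residual prediction to 1e-4 K), and reports mean absolute attributions
overall and per region.

## Thermodynamics

Saturation vapor pressure uses the Bolton exponential form over liquid water
for all temperatures — one consistent curve, no ice-phase branch, matching
the defaults of the tools this pipeline is meant to be compared against. Dew
point from specific humidity inverts that curve after
$e = qp/(\varepsilon + (1-\varepsilon)q)$ with $\varepsilon = 0.622$; the
closed-form inverse round-trips with the forward map to well under 0.001 K
across 250–305 K. Relative humidity is $100\,e_s(T_d)/e_s(T)$, clipped to
100% with a warning for supersaturated input (consistent with the
non-dropping cleaning policy). The heat index follows the US NWS convention:
the simple Steadman average below 80 °F and the Rothfusz regression with the
published low-RH and high-RH adjustments at or above it, with all constants
in one table. The published formula pair is genuinely discontinuous at the
80 °F gate: the mismatch is negligible at moderate humidity but reaches
roughly 2.5 K near RH 90%, and the tests assert that measured behavior
rather than pretending the seam away.

## The synthetic study

Because the real national archives are not reproducible at desk scale, the
package ships a generator whose outputs exercise every ingestion path with
known ground truth. True dew point is a sum of: a smooth spatial field
(random-direction sinusoids; the wavelength calibration makes
`length_scale_km` the distance at which spatial correlation falls to 1/2), a
slow temporal component, a diurnal harmonic, and local covariate effects
(elevation lapse, distance-from-water decay, and optionally a
piecewise-constant mid-elevation band effect). Temperature is constructed at
least 2 K above dew point, with noisy observations allowed to supersaturate
so the diagnostic path is exercised. Terrain gets its own, shorter length
scale (default 120 km) than the moisture field (500 km), reflecting that
terrain varies faster than synoptic moisture — and giving interpolation
something it genuinely cannot recover.

The gridded predictors see only the smooth component plus a smooth bias
field, emulating reanalysis products that do not resolve local land-use
signals; the coarse grid is the exact 2×2 block mean of the fine grid
(0.2°/0.4° by default — block-mean nesting requires a 2× ratio, so the real
products' 0.1°/0.125° pair is represented by a nested stand-in), a western
"coastal" band of the fine grid is masked to exercise the fallback, and CWV
is a monotone transform of late-morning/early-afternoon dew point with noise
and a random cloud mask written into QA bits.

Two named scenarios define the study conditions. The **default scenario**
(150 stations on an 8°×6° box, 30 days, 8 observations/day, 1 K observation
noise, moderate linear effects) sizes the full CV suite to minutes on one
CPU; because the T-max DV inherits the full 1 K noise of a single
observation, its CV RMSE is expected to approach that floor from above. The
**nonlinear scenario** (`synthetic_config_nonlinear()`: 100 stations, 20
days, doubled linear effects and a 5 K mid-elevation band) is built so the
three model families separate: the band is nearly orthogonal to the linear
elevation term, so OLS cannot absorb it, while the short terrain scale puts
the covariate effects below IDW's resolution.

What the generator does **not** emulate — and what passing tests therefore do
not establish about real data: seasonal cycles beyond the study window,
heteroskedastic or temporally correlated observation error, station dropout
and metadata errors, real quality-control flag vocabularies, non-Gaussian
reanalysis bias, or the climatology of any actual region. The generator
validates the machinery, not the meteorology.

## Numerical conventions and limitations

* All ties break deterministically (earliest time, lowest grid index).
* The spherical-earth distance (radius 6371 km) errs below 0.5%, immaterial
  relative to IDW smoothing.
* Station-day tables, statics, regions and grids all serialize as plain CSV.
* Test-suite problem sizes: most property tests run on a 30-station, 6-day
  bundle; the CV-integrity and noise-floor checks use the default scenario;
  the model-ordering check runs ten replicates of the nonlinear scenario.
* Known limitations: accuracy degrades where the network is sparse (the IDW
  anchor weakens) and near grid edges/coasts (coarse fallback); extrema DVs
  are noisier than the mean DV; the framework is interpolative — forecasting
  and counterfactual land-cover analyses are out of scope.
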