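---
title: "From satellite columns to surface NO2 and attributable mortality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From satellite columns to surface NO2 and attributable mortality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

Ground NO2 monitors are sparse and, in most places, recent; satellite
instruments retrieve the tropospheric vertical column density (VCD) of NO2
daily, everywhere, and for much longer. `satno2` implements the chain that
turns these two sources into a long gridded surface-concentration record
and a mortality burden:

1. **Ground QC** — clean hourly monitor data down to station-monthly means.
2. **Gap-filling** — impute cloud-masked satellite pixels so the column
   record is complete.
3. **Scaling-factor ensemble** — regress the ratio
   $S = \mathrm{NO_2^{surface}} / \mathrm{VCD}$ on covariates with three
   tree-ensemble learners, convert each learner's prediction back to a
   surface concentration by $\hat{\mathrm{NO_2}} = \hat{S} \times
   \mathrm{VCD}$, and combine the three predictions with a generalized
   additive model (GAM).
4. **Validation** — sample-based, spatial, temporal, and by-year
   cross-validation, plus a held-out final year (hindcast).
5. **Summaries and burden** — population-weighted exposure statistics and
   counterfactual attributable deaths
   $AD = \frac{RR_C - 1}{RR_C}\,\mathrm{Pop}\,I$ with
   $RR_C = RR^{(C-\mathrm{ref})/10}$.

Because the real inputs are multi-terabyte archives, the package ships a
*synthetic world generator* that reproduces the statistical structure the
method relies on. Every latent quantity (true surface field, true scaling
factor, injected artifacts, suppression factors) is retained, so each
stage can be tested as a parameter-recovery problem.

# The synthetic world

`world_config()` fixes the study conditions. The defaults describe a
16-year run (2005–2020) on a 60×60 fine grid at 0.05°, with 0.25°
satellite pixels (5×5 fine cells), 15 monitors, and 8 simulated days per
month. The sizes are desk-scale analogues of the real setting: 15 monitors
on 3,600 cells matches the real network's density of roughly one station
per 250 fine cells, and the idealised 8-day month preserves the
daily-to-monthly aggregation structure (daily day-factors are normalised
so their monthly mean is exactly one) while keeping ~1,500 daily forest
fits affordable.

The truth fields are built from minimal ingredients:

* **Surface NO2** = (smooth background + exponential-decay hotspots) ×
  seasonal sinusoid (winter maximum, amplitude 0.35) × piecewise-linear
  trend rising to a peak at year index 7 and declining thereafter ×
  a 0.8 suppression in months 1–4 of the final year (a "lockdown").
* **Scaling factor** $S$ = 20·exp(−0.35·BLH) × a domain-wide monthly
  lognormal anomaly (σ = 0.06). The boundary-layer covariate (BLH) makes
  the regression well-posed; the monthly anomaly is meteorological
  variability the covariates do *not* explain, which is what separates
  temporal from sample cross-validation skill.
* **Columns**: VCD = surface / S at fine scale, block-averaged to the
  satellite grid; daily columns are the monthly column times a shared
  day factor (lognormal σ = 0.08). Retrieval noise is multiplicative
  lognormal with σ = 0.10 — the real instrument's noise level is not a
  published constant, so it is an exposed parameter rather than an
  asserted value.
* **Covariates**: temperature and BLH (seasonal + smooth spatial noise),
  an emission proxy following the spatial pollution pattern and trend,
  elevation, annual population (1.5 %/yr growth), and a
  reanalysis-column analogue `cams_no2` (the true fine column with 15 %
  smooth multiplicative error), playing the role modelled columns play
  for the real gap-filler.
* **Clouds**: an AR(1)-in-time, spatially smoothed Gaussian field, mixed
  with the (standardised log) column pattern with weight 0.35 and mapped
  through a probit so that the fraction of pixel-days with cloud
  fraction > 0.30 matches `missingness_target` (default 0.53). Gaps are
  therefore spatially coherent and concentrated over polluted cells —
  missingness is non-random, the hard case for imputation.
* **Monitors** are placed with probability ∝ population^bias (bias 1 by
  default, emulating urban-heavy siting) and carry a per-station
  lognormal siting bias (σ = 0.12) — the site-specific increment a model
  cannot learn for unmonitored places — plus a diurnal cycle, additive
  hourly noise (σ = 3 µg/m³) and a detection-limit floor. Two percent of
  station-days carry injected artifacts: stuck runs of 8–12 identical
  hours, or days truncated below 18 valid hours. Artifact positions are
  recorded; the generator nudges run-adjacent values that would
  round-match so that artifact bookkeeping is exact.
* **Demography**: nine rectangular provinces; the provincial table stops
  one year short of the simulation (reporting lag), so the burden module's
  carry-forward rule is exercised.

What the generator does **not** emulate: real geography and chemistry,
transport, instrument drift, correlated retrieval biases, within-cell
exposure gradients, or monitor relocations. Passing recovery tests on
this world shows the chain is implemented correctly and identifiable
under its stated assumptions — not that the real-data accuracy figures
transfer.

# Ground QC

The three rules, in fixed order after the reference-state correction
(×0.92 strictly before 2018-09-01, the month boundary on which the
reporting convention changed):

1. runs of ≥ 8 consecutive identical values (equality after rounding to
   3 decimals; a missing hour breaks a run) are removed as instrument
   malfunction;
2. days with fewer than 18 valid hours (75 %) are dropped;
3. months with fewer than 20 valid days are dropped.

The daily rule is applied to hours *surviving* stuck-run removal. On the
synthetic 8-day months the monthly threshold scales to 6 days (75 %); the
function default remains 20 for real-length months. The multiplicative
correction cannot create or destroy identical runs, so the fixed order
does not change what is flagged.

# Gap-filling

One random forest per day (mtry 5, 500 trees), trained on all observed
pixel-days in the rolling 3-day window centred on the target day and
predicting that day's missing pixels; edge days use the truncated window.
Predictors: the reanalysis column analogue, cloud fraction, temperature,
BLH, emission proxy, elevation, population, and spatiotemporal terms
(lat, lon, day offset within the window, day of year). Observed pixels
are never altered. Skill is reported as the forest's out-of-bag R² per
day, both averaged over days and pooled over OOB predictions, since
either convention is defensible. Days with fewer than max(10, mtry+1)
training pixel-days fall back to same-day spatial IDW, then to per-pixel
temporal interpolation, so the record is complete by construction; the
fallback is logged, never silent.

# Gridding

IDW with power 2 over the k = 4 nearest non-missing source centres
(neither parameter is prescribed by the method's sources; both are
exposed). Distances are Euclidean in degrees — adequate on a small
domain — with a haversine switch for realism. A destination centre
within 1e-9° of a source centre takes the source value exactly, so
regridding a grid onto itself is the identity on observed cells.
Monthly fine columns are produced in the order: fill daily → monthly
mean on the coarse grid → IDW to 0.05°.

# The ensemble exposure model

The regression target is the scaling factor S rather than the surface
concentration itself; multiplying a predicted S by the (observed or
imputed) column recovers the concentration and lets the column carry the
spatial signal. Rows with non-finite S or with columns at or below the
1st percentile of positive values (where the ratio is ill-conditioned)
are excluded and counted.

Base learners, all fit on S with 500 trees: a random forest
(variables-per-split 15, capped at the number of available predictors —
the synthetic stack has 11) and two gradient-boosted tree variants of
maximum depth 10 (learning rates 0.1 and 0.05, the slower one
row-subsampled at 0.7). The combiner is a GAM of observed NO2 on the
three base NO2 predictions, one thin-plate smooth per prediction. A
smooth's unpenalised null space spans the linear term, so the combined
in-sample fit can never be worse than the best base learner (the
penalised residual sum of squares is bounded by that of the
linear-terms-only least-squares fit) — this containment is tested
numerically.

Whether the combiner should see in-sample or out-of-fold base
predictions is genuinely open; standard stacking practice favours
out-of-fold, so that is the default (internal 10-fold split), with
`combiner = "insample"` available for comparison. Inside
cross-validation folds the combiner is refit on in-sample predictions of
that fold's training data — still leakage-free across folds — to avoid
nesting a second split; this is a cost choice recorded here.
Negative combined predictions are clipped to zero and counted.

# Validation

Folds are unit-level random partitions dealt round-robin: rows (sample),
whole stations (spatial), whole calendar year-months (temporal), or one
fold per year (by-year). "Months" means year-months of the run, not
months-of-year, matching the idea of predicting unmonitored times.
Metrics are pooled over the assembled out-of-fold predictions:
R² = 1 − SS_res/SS_tot (which can be negative; the squared-correlation
variant is available but not the default) and RMSE. External validation
fits on all years but the last and evaluates the final year; any overlap
of train and test years is an error. The expected ordering — sample ≥
temporal ≥ spatial R² — follows from the generator's design: the monthly
anomaly is invisible to temporal CV and the station siting bias to
spatial CV.

# Summaries and burden

Population-weighted means, strict-exceedance population fractions
(thresholds such as the WHO annual guideline 10 µg/m³ and interim target
1 at 40 µg/m³), meteorological-season means (DJF winter with December
assigned to the following winter), and period relative changes
(pw-mean(a) − pw-mean(b))/pw-mean(b). Annual means require all 12 months.

The burden module uses the log-linear exposure-response
RR per 10 µg/m³ = 1.02 (95 % CI 1.01–1.04) for all-cause mortality with
a zero counterfactual reference. Exposures below the reference clamp to
RR = 1 (no protective extrapolation; moot at ref = 0). Provincial
exposure is the population-weighted (not area-weighted) annual mean over
the province's cells, since burden scales with exposed persons; CI bounds
substitute the RR bounds (no Monte Carlo, matching single-RR reporting);
demography years missing from the table carry the last available year
forward. A fixed-reference variant freezes population and mortality at a
chosen year to separate exposure trends from population growth.

# Numerical choices and problem sizes

* All stochastic fits are single-threaded with explicit seeds; a world,
  its observations, and every model fit are bit-reproducible functions of
  the configuration seed.
* Tests run the full chain on the default world (60×60×192 months,
  1,536 satellite days, 15 stations) once and reuse the artifacts; the
  cross-validation ordering check uses the 2014–2019 training table
  (~1,070 rows) over five fold seeds. These sizes were chosen once as
  the smallest world on which the spatial/temporal/sample distinctions
  are statistically visible.
* Equality of "identical" hourly values uses 3-decimal rounding: stuck
  instruments emit byte-identical values, while float noise in synthetic
  data must not create accidental runs.
* Degenerate inputs fail loudly: all-missing fields, empty seasons or
  periods, zero regional population, constant regression targets,
  missing demography keys.

# Known limitations

* The GAM containment guarantee applies to the in-sample-trained
  combiner; the default out-of-fold combiner trades a few per cent of
  in-sample fit for honest stacking.
* IDW in degree space ignores meridian convergence; switch to haversine
  distances for large or high-latitude domains.
* The synthetic world's covariates are far more informative than real
  predictor stacks (notably the reanalysis-column analogue); recovery
  R² here is an upper bound on what identical code achieves on real
  archives.
* The burden calculation is all-cause, single-pollutant, and
  age-unstratified by design.
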