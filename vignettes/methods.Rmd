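---
title: "Methods: critical-slowing-down indicators of forest resilience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: critical-slowing-down indicators of forest resilience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcsd)
```

## The indicator and its assumptions

Near a tipping point a system's recovery rate from small perturbations
declines — critical slowing down — and its state variable becomes more
autocorrelated. `forestcsd` measures this on vegetation-index time
series. The state proxy is the kernel NDVI, `kNDVI = tanh(NDVI²)`, a
bounded, saturation-resistant productivity proxy; the indicator is the
lag-1 temporal autocorrelation (TAC) of its stationary anomalies, and
the dynamic indicator is the linear trend (δTAC) of TAC computed on
annual 3-year trailing windows. Three assumptions matter:

* **Stationarity after preprocessing.** TAC is meaningful only on
  anomalies free of seasonal cycles and long-term trends; the anomaly
  pipeline (climatology removal, then per-pixel OLS detrending) is
  responsible for this, and its residual biases propagate directly into
  TAC.
* **AR(1)-like short-term dynamics.** The interpretation of lag-1
  autocorrelation as inverse recovery rate presumes roughly first-order
  linear relaxation between composites. The synthetic generator makes
  this literal; real canopies only approximate it.
* **Separability of forcing autocorrelation.** Autocorrelated climate
  forcing raises the autocorrelation of the response without any change
  in ecosystem recovery rates. The factorial counterfactual
  (`factor_out_climate_ac()`) removes the part of annual TAC explained
  by the climate-autocorrelation predictors through the fitted random
  forest, under a space-for-time analogy: one global model fitted on
  long-term spatial variation is applied per year.

## Pipeline and parameters

The stages, each an exported function with the thresholds shown:

| stage | function | key parameters (default) |
|---|---|---|
| anomalies | `compute_anomalies()` | quality classes kept `{0,1}`; ≥ 2 obs per 16-day period for a climatology |
| gap fill | `gap_fill()` | climatological fill (anomaly 0), flagged |
| mask | `apply_forest_mask()` | forest cover > 0.05; missing fraction < 0.5 |
| TAC | `long_term_tac()`, `rolling_tac()` | window 3 yr (trailing), ≥ 20 valid pairs |
| trend | `tac_trend()` | OLS vs calendar year, ≥ 10 annual values |
| decadal | `decadal_difference()` | split year 2011 |
| attribution | `fit_attribution_model()` | 100 trees, 60/40 split, CV grid over mtry {p/3, p/2, 2p/3} × depth {∞, 8} |
| counterfactuals | `factor_out_climate_ac()`, `driver_contributions()` | groups frozen at first-year values |
| climate space | `bin_climate_space()` | 50×50 bins, 1st–99th percentile edges, ≥ 50 records, cos(latitude) weights |
| declines | `detect_ad()` | severities 1–6σ, 10-yr antecedent window, strict inequality, first occurrence |
| early warning | `antecedent_trend()`, `sample_control()`, `conditional_probability()` | trend over years < t, ≥ 8 values; 8-neighbour controls; strict-exceedance count |
| threshold | `extract_tac_ad()`, `fit_threshold_model()`, `proximity()` | 3σ events, antecedent δTAC > 0, 10 reduced predictors |

The `min_pairs = 20` floor per 3-year window (of at most 68 pairs) keeps
single-window TAC estimates from being dominated by a handful of winter
observations; the `min_years` floors play the same role for trends. The
predictor windows in annual mode are the same trailing 3-year windows as
the TAC they explain.

Two derived metrics close the threshold analysis: *tolerance*
`TAC_AD − mean TAC(first decade)`, the autocorrelation increase an
ecosystem absorbs before its decline, and *proximity*
`TAC_AD − TAC(final year)`, which is zero or negative once the critical
level has been reached. The sign convention follows the stated rule
(negative = threshold overpassed); the aridity axis for tolerance uses
the De Martonne index `P/(T + 10)` (mm °C⁻¹), consistent with the
reported unit of the gradient, binned on fixed 0–500 edges in steps of
100.

## What the synthetic generator emulates

`build_scene()` draws a four-region latitudinal study area (boreal,
temperate, arid, tropical) in which every pixel has

* an NDVI-like series at 23 composites per year (day-of-year 1, 17, …,
  353): baseline + sinusoidal seasonal cycle + linear greening trend +
  AR(1) anomalies whose coefficient φ may drift linearly in time
  (`phi0`, `phi_trend`), with `noise_sd` the *stationary* anomaly
  standard deviation (innovations are scaled by √(1−φ²));
* missing-data flags, missing-completely-at-random at an exact per-pixel
  fraction (snow- and cloud-prone regions get more);
* monthly climate drivers as AR(1) anomalies around jittered regional
  means with controlled CV and lag-1 autocorrelation, plus a seasonal
  temperature cycle;
* annual forest cover, an intact/managed label with an exact per-region
  intact fraction, a per-region growing-season month mask, and annual
  GPP that is affine in the standardized growing-season kNDVI state
  (coupling in [−1, 1]) plus noise — the minimal generative form of a
  mutual GPP–resilience link;
* optional injected abrupt declines: a persistent step change in kNDVI
  space sized so the target year's growing-season mean lands exactly
  `severity·σ` (plus a strict-exceedance ε of 10⁻⁶) below the 10-year
  antecedent mean, so the detector recovers injections at their planted
  severity.

The default region parameters describe realistic magnitudes: AR(1)
levels of 0.20–0.35, φ drifts of order ±1.5 × 10⁻³ yr⁻¹ (positive in
tropical/temperate/arid, negative in boreal), missingness of 10–30%,
and region-appropriate climate and GPP levels. What the generator does
*not* emulate: spatial correlation of the fields (pixels are independent
unless the optional box-kernel `spatial_smooth` is enabled),
non-sinusoidal phenology, quality-flag structure correlated with the
state (snow gaps can be made contiguous in winter only through the
missing-at-random approximation), sensor saturation and bias, and any
real disturbance agent. Passing tests therefore demonstrate that the
estimators recover the statistical structure they target — not that
real-data artifacts (mixed pixels, orbit drift, snow contamination)
are handled.

## Numerical choices

* **Detrending abscissa.** The linear detrend regresses anomalies on the
  *year centre*, not on fractional year. After climatology removal the
  deterministic part of any linear drift is constant within a year
  (the within-year part of the ramp is absorbed into the 23 period
  means), so the annual abscissa removes a pure ramp exactly and makes
  the anomaly operator idempotent; a sub-annual abscissa leaves a
  sawtooth residual.
* **TAC estimator.** Pearson correlation of (x_t, x_{t+1}) pairs over
  pairs whose members are both valid, computed from moment sums (exactly
  `cor()` on the paired values). Gap-filled zeros are included by
  default — matching the gap-fill-then-compute order — with
  `use_gapfilled = FALSE` to exclude them. Filling with the climatology
  attenuates TAC toward zero (zeros dilute the lagged covariance); this
  is a documented property with a paired-simulation test, and the
  trend-recovery calibration below therefore uses gap-free pixels.
* **Degenerate inputs.** Constant series have undefined TAC → NA;
  constant climate has CV 0 and its undefined autocorrelation is set to
  0 and flagged (`ac_flagged`); CV with a near-zero mean floors |mean|
  at 10⁻⁶. Zero-variance t-test samples take p = 0 (nonzero mean) or
  p = 1 (zero mean). Exact-zero trends classify as positive in the
  δGPP/δTAC quadrants. Ties in the conditional-probability count are
  non-exceedances by default (`ties = "half"` gives half credit).
* **Determinism.** Forests use `ranger` with a fixed seed and one
  thread; the calibration/validation split, CV folds, per-bin matching
  subsamples and control-pixel draws are all seeded. A pipeline rerun
  with the same configuration reproduces the manifest hash and outputs
  bit for bit.
* **Edges.** Climate-space bin edges span the 1st–99th percentile of the
  pooled climate (uniform spacing); block aggregation averages partial
  edge blocks over their available cells; rolling windows are trailing
  (`[t−2, t]`), with the first two years undefined.

## Design choices where the design was open

* Managed/intact matching draws equal-size per-bin subsamples (seeded)
  from the larger class within each shared climate bin, rather than
  pairing bin means; this preserves within-bin dispersion for the Welch
  test.
* Control pixels for abrupt-decline events come from the 8-neighbourhood
  only; events with no undisturbed neighbour are dropped rather than
  searched at larger radius, keeping the "similar background climate"
  guarantee strict.
* The windowed GPP–TAC correlation pools all pixel-year pairs inside the
  spatial window (≥ 30 pairs) rather than averaging per-pixel
  correlations, sampling the joint distribution instead of noisy
  per-pixel estimates, and uses the enhanced TAC by default.
* Hyperparameter search is a deterministic cross-validated grid; the
  sizes of a stochastic optimizer's search space would otherwise be an
  unreproducible degree of freedom.
* GPP is extrapolated to the final year by per-pixel OLS over all
  available annual values before summing exposure over the critical
  mask.

## Problem sizes and what the tests show

The test suite and acceptance script run on desk-scale scenes chosen so
each property is measured with useful precision in seconds: estimator
calibration on 500 pixels of 21 years × 23 composites; trend recovery on
a 40×40 gap-free scene with a planted +0.015 yr⁻¹ φ drift; null
calibration of the bin-level t-test on 800 bins × 20 stationary pixels;
attribution sanity on 900–2000 records; early-warning calibration on
60×60 scenes yielding ~450 decline events; the planted φ = 0.5 threshold
on 400 pixels; matched-class recovery on 4000 + 4000 records. These
sizes put the Monte-Carlo error of each checked quantity well inside its
acceptance band; they are orders of magnitude below a global 0.05°
analysis, so absolute values (e.g. a validation R² on a 256-pixel scene)
are not comparable to archive-scale fits.

## Known limitations

* The factorial counterfactual inherits the random forest's inability to
  extrapolate beyond the training range of the frozen predictors; annual
  predictor excursions outside the long-term spatial range are clamped
  by the trees, biasing contributions toward zero there.
* Gap-filling with climatological values attenuates TAC
  multiplicatively with the fill fraction; comparisons across pixels
  with very different missingness conflate resilience with data
  availability (the mask's 50% ceiling bounds, but does not remove,
  this effect; `use_gapfilled = FALSE` trades it for fewer pairs).
* Pixel-level δTAC significance is deliberately not computed; inference
  lives at the bin level, where the 3-year-window serial dependence of
  annual TAC does not enter the sampled trend distribution.
* Critical conditions (proximity ≤ 0 with δTAC > 0) indicate threshold
  exceedance of the empirical TAC_AD, not a confirmed regime shift.
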