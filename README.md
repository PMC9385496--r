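# forestcsd

Critical-slowing-down (CSD) indicators of forest resilience from gridded
vegetation-index time series.

When an ecosystem drifts toward a tipping point its recovery from small
perturbations slows down, and this slowing is visible as rising lag-1
temporal autocorrelation (TAC) in its state variable. `forestcsd`
implements this idea as a complete, testable pipeline for satellite-style
inputs: it turns an NDVI-like 16-day raster time series into stationary
kNDVI anomalies, estimates TAC over the full record and over annual
3-year rolling windows, removes the confounding autocorrelation of the
climate forcing with random-forest factorial counterfactuals, and uses
the trend of the resulting *enhanced* TAC (δTAC) as the resilience
indicator. On top of that it detects abrupt declines (ADs) in the
growing-season vegetation state, tests δTAC as an early-warning signal
against matched undisturbed controls, and estimates how close undisturbed
forest is to its empirical critical threshold TAC_AD. Everything is
exercised end to end on a synthetic-scene generator with per-pixel ground
truth, so each stage can be validated against known parameters — the
package is aimed at researchers studying ecosystem resilience and
early-warning signals who need a tested reference implementation of this
methodology.

## The model in brief

Vegetation state is summarized by the kernel NDVI,

    kNDVI = tanh(NDVI²),

deseasonalized by subtracting the multi-year 16-day climatology and
detrended by per-pixel OLS. The resilience indicator is the lag-1
autocorrelation of the anomalies x(t):

    TAC = cor(x_t, x_{t+1}),

computed long-term (full record) and annually over trailing 3-year
windows. Long-term TAC is related to 14 environmental predictors (forest
cover and growing-season kNDVI; mean, CV and lag-1 autocorrelation of
precipitation, temperature, evapotranspiration deficit and solar
radiation) by a random forest

    TAC = f(X) + ε_f ,

and the part of the annual TAC signal driven by climate autocorrelation
is removed by the factorial counterfactual

    TAC^t | X_ac = f(X^t) − f(X^t with X_ac frozen at its first-year value),

whose subtraction from the raw annual series yields the enhanced TAC.
δTAC is the OLS slope of that series. An abrupt decline at severity n·σ
is the first year whose growing-season mean falls more than n antecedent
standard deviations below the 10-year antecedent mean. TAC_AD — the TAC
in the year preceding an AD on pixels with rising antecedent δTAC — is
extrapolated to undisturbed pixels with a second random forest
`TAC_AD = g(X_reduced) + ε_g`, and the proximity `TAC_AD − TAC(final)`
(≤ 0 once the threshold is reached) defines, together with δTAC > 0, the
critical conditions whose extrapolated GPP exposure is reported.

## Worked example

```r
library(forestcsd)

cfg <- run_config(scene = scene_config(grid_shape = c(16, 16), seed = 7),
                  nbins = 10, min_bin_count = 5)
run <- run_pipeline(cfg)
print(run)
#> <csd_run> stages: simulate, preprocess, tac, attribution, climate_space, interplay, abrupt_decline
#>   config hash: 4acc4d9c8ea6396ae8f91f4154690254
#>   long-term TAC: mean 0.232 over 256 pixels
#>   attribution model: validation R2 = 0.425

print(run$attribution$model)
#> <rf_attribution> 100 trees, mtry = 5, depth = unlimited; n = 256 (154 calib / 102 valid)
#>   validation: R2 = 0.425, MSE = 0.005277, PBIAS = -6.04%

tapply(run$attribution$delta_tac, run$scene$region, mean, na.rm = TRUE)
#>        boreal     temperate          arid      tropical
#> -0.0008212809  0.0009418559  0.0018223455  0.0024928691
```

The δTAC means recover the scene's planted drift pattern: the default
generator gives tropical, temperate and arid pixels a slow positive
per-year drift of the AR(1) coefficient and boreal pixels a negative one,
and the indicator reproduces both the signs and the ordering. The
long-term TAC mean (0.232) reflects the region-level AR(1) coefficients
(0.20–0.35) after the mild attenuation caused by gap-filling flagged
observations with climatological values.

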