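Package: forestcsd
Title: Critical-Slowing-Down Indicators of Forest Resilience from
    Vegetation-Index Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify forest resilience from gridded
    vegetation-index time series using critical-slowing-down theory.
    Computes lag-1 temporal autocorrelation (TAC) of deseasonalized,
    detrended kNDVI anomalies, annual rolling-window TAC and its trend
    (dTAC), random-forest attribution of TAC to environmental drivers
    with factorial counterfactuals that remove the confounding
    autocorrelation of climate forcing, climate-space binning and
    matched managed-versus-intact comparisons, GPP-resilience interplay
    metrics, abrupt-decline detection with early-warning statistics,
    and proximity of undisturbed forests to their empirical critical
    resilience threshold. Includes a synthetic-scene generator with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
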