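Package: satno2
Title: Satellite-Derived Surface NO2 Exposure Modelling and Mortality Burden
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating ground-level nitrogen dioxide (NO2) from
    satellite tropospheric column densities and assessing the attributable
    mortality burden. Implements quality control of hourly ground monitor
    data, random-forest gap-filling of cloud-masked satellite columns on a
    rolling three-day window, inverse-distance-weighted regridding, an
    ensemble exposure model that regresses surface-to-column scaling factors
    with three tree-ensemble base learners combined by a generalized
    additive model, sample/spatial/temporal/by-year cross-validation,
    population-weighted exposure summaries, and counterfactual
    attributable-death calculations with relative-risk confidence bounds.
    A self-contained synthetic-world generator with known truth fields
    supports end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    xgboost,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
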