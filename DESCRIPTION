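Package: riacarb
Title: Carbonate-System Time Series Reconstruction for a Coastal Embayment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs multi-decadal weekly time series of pH, hydrogen-ion
    concentration and total alkalinity in an upwelling-influenced coastal
    embayment from hydrographic predictors (temperature, salinity, nutrients,
    position, time) using ensembles of Bayesian-regularized feed-forward
    neural networks, and extracts salinity-normalized, seasonally detrended
    long-term linear trends with confidence intervals. Includes a fully
    specified synthetic-hydrography generator with planted ground truth so
    that every stage of the pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
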