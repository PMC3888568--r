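Package: heatmort
Title: Projection of Heat-Wave-Attributable Excess Mortality with
    Uncertainty Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: County-level projection of excess mortality attributable to
    future heat waves. Calibrates modeled daily temperature series against
    station observations by ratio methods with spatial interpolation
    (fixed 150-km search radius or five nearest neighbours), detects heat
    waves under four operational definitions (heat-index based, daily
    mean, daily maximum following Meehl-Tebaldi, and daily minimum),
    estimates excess deaths from region-specific attributable risks
    sampled by Latin hypercube, and apportions the variance of the
    resulting estimates across scenario factors with first-order
    sensitivity indices. A seeded synthetic-data module generates
    counties, temperature fields, station records, and demography with
    the statistical structure the analysis assumes, so the full pipeline
    runs and is testable without external climate or census data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
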