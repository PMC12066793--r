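Package: estrade
Title: Ecosystem-Service Trade-Off Mapping and Driver Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A raster pipeline for quantifying ecosystem-service trade-offs in
    data-sparse arid landscapes. Quantifies four services per year from driver
    rasters (Budyko/Zhang water yield, RUSLE soil conservation, RWEQ windbreak
    and sand fixation, InVEST-style habitat quality), classifies pairwise
    trade-offs and synergies by partial correlation with t-test significance,
    maps trade-off intensity as the root-mean-square deviation of standardized
    services, and attributes intensity to ten landscape drivers with a
    gradient-boosted tree ensemble and Shapley additive explanations, including
    nonlinear threshold extraction from attribution dependence curves. A seeded
    synthetic-county generator produces co-registered multi-year driver stacks
    with the spatial and temporal structure the analysis assumes, so every
    stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
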