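Package: prenatalDLM
Title: Prenatal Air Pollution Exposure Windows and Epigenetic Gestational Age Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for studying associations between
    prenatal ambient air pollution and epigenetic gestational-age acceleration
    at birth. Provides inverse-distance-squared (IDW2) interpolation of weekly
    monitor-station concentrations to maternal residences with nearest-station
    selection rules, aggregation to preconception/trimester/pregnancy exposure
    windows, linear-predictor cord-blood epigenetic clocks with gold-standard
    quantile calibration, reference-based cell-type deconvolution, residual age
    acceleration, period-average regression models with change-in-estimate
    confounder screening, and weekly distributed-lag models built on a natural
    cubic spline lag basis with delta-method confidence intervals. A seeded
    synthetic-cohort generator emulates monitor networks, residential
    histories, covariates and methylation beta matrices with planted effects so
    every stage can be exercised and validated without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
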