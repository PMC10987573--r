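Package: disparitymap
Title: Statistical Mapping of Community Health Disparities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing health-outcome disparities across the
    community areas of a geographic catchment. Reads region-level tables
    and boundary polygons, selects a best-fit normality transform per
    variable by the Pearson chi-square statistic over its degrees of
    freedom, removes outliers by the 1.5-IQR fence rule, reports crude and
    cleaned correlations with Fisher-z intervals, screens and adjusts for
    confounders via the 10 percent change-in-estimate rule and partial
    correlation, fits standardized multivariate models (linear, logistic,
    lasso) with percent-contribution feature importance, and renders
    choropleth maps as SVG or HTML. Includes a synthetic-data generator
    with known correlation and confounding structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nortest,
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
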