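Package: bpphealth
Title: Predicting Census-Tract Health Effects of Bicycle and Pedestrian Paths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating how many percentage points a specified
    addition of bicycle and pedestrian path mileage will improve census-tract
    health outcomes. Implements an iterative exploratory factor analysis with
    communality-based variable filtering, confirmatory factor analysis on a
    held-out half of tracts, regression-method factor scoring, a
    threshold-based neighbor-matching prediction algorithm with a mileage
    increment sweep, and an evaluation harness comparing the method against
    predict-no-change and linear-regression baselines (MAE/RMSE with bootstrap
    standard deviations and one-tailed paired t tests). Includes a synthetic
    city-panel generator with planted three-factor structure, a mileage
    intervention, and a lagged threshold-shaped outcome response for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
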