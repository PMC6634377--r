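Package: forageshed
Title: Nutritional Landscape Analysis for a Large Browser
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking forest condition to the nutritional landscape
    of a large browsing ungulate (Shiras moose). Computes digestible energy
    and protein of forage shrubs from chemistry assays and classifies species
    into quality classes; corrects microhistological fecal diet proportions
    for digestibility; converts shrub transect measurements into crown-volume
    densities and calibration regressions; fits penalized presence and volume
    models with repeated cross-validation and sensitivity-equals-specificity
    thresholds; aggregates predicted forage volume to management units,
    back-casts covariates to reconstruct past forage, and correlates a
    harvest-based population-trend index with forage metrics. A seeded
    synthetic-data module emulates every input so the whole pipeline is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    vegan,
    yaml,
    zoo
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
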