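Package: wvcrisk
Title: Wildlife-Vehicle Collision Risk from Exposure and Hazard Submodels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the risk of wildlife-vehicle collisions on a road
    network by decomposing it into exposure (relative likelihood of
    species occurrence, fitted with boosted regression trees) and hazard
    (traffic volume and posted speed, fitted with random-forest
    regressions), combined in a complementary log-log binomial GLM
    derived from a Poisson encounter process. Includes a synthetic-scene
    generator with known ground truth (autocorrelated covariate rasters,
    road networks, presence/background points, traffic observations and
    simulated collision outcomes), grid-based road segmentation and
    raster sampling, sequential deviance decomposition, hold-out ROC
    validation, and export of per-segment risk maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xgboost,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
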