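Package: imspeak
Title: Automated Peak Detection, Alignment and Classification for MCC-IMS Breath Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated analysis pipeline for multi-capillary column ion
    mobility spectrometry (MCC-IMS) breath measurements: reactant-ion-peak
    compensation and Savitzky-Golay smoothing, peak picking on single 2D
    intensity matrices (local maxima, Savitzky-Golay Laplace-operator filter
    thresholding regions, slope-analysis segment detection), cross-measurement
    peak clustering into consensus features (grid squares, DBSCAN, weighted
    cluster editing, fixed-variance EM with component merging), feature-matrix
    construction, and repeated stratified nested cross-validated AUC
    benchmarking with rank-sum comparison of full pipelines. Includes a
    synthetic two-class cohort generator with ground truth so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
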