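Package: mfgait
Title: Multifractal Gait-Stability Analysis and Fall-Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multifractal detrended fluctuation analysis (MF-DFA) of motion
    trajectories with the singularity-spectrum asymmetry statistic D(alpha)
    as a per-joint motion-stability index. Provides a synthetic motion-capture
    cohort generator (42 anatomical markers in three planes at 60 Hz, with
    tunable multifractal width and group separation), extraction of the
    126-dimensional stability feature matrix, group statistics (per-channel
    t-tests, sex-by-fall-status comparisons, baseline rank-sum checks), and a
    six-classifier fall-risk benchmark (L1/2 sparse kernel iteration, SVM,
    gradient boosting, random forest, and small feed-forward and recurrent
    networks) with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
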