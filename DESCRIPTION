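Package: stressci
Title: Composite Stress Indices from Wearable Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing acute and chronic mental stress from a
    wearable four-biomarker panel (sweat cortisol, sweat glucose, skin
    temperature, heart rate). Implements circadian baseline fitting with
    leave-one-out model selection and retro-adjustment of measurements to a
    benchmark clock time, three composite stress indices (an unweighted
    relative-change sum, a regression-weighted temporally coupled index
    classified against STAI-S cutpoints, and a machine-learning stage for
    chronic-stress classification and regression), pulse-waveform heart-rate
    extraction via zero-phase band-pass filtering and peak detection, and a
    seeded synthetic-cohort generator that emulates the statistical structure
    of the underlying study designs so every stage is testable without
    clinical data.
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
    minpack.lm,
    nnet,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr,
    yaml
Config/testthat/edition: 3
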