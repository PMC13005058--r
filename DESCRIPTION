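Package: mcidrive
Title: Naturalistic Driving Digital Biomarkers for Early Cognitive Impairment Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline that turns raw in-vehicle sensor
    streams (1 Hz GPS, 24 Hz accelerometer and gyroscope) into trip- and
    turn-level multivariate time series and classifies drivers as cognitively
    healthy or mildly impaired. Includes a synthetic driving-cohort generator
    with controllable, sporadically expressed impairment signatures; trip
    segmentation, cross-sensor completeness checks and 1 Hz synchronization;
    GPS turning-maneuver detection with fixed-length windowing; a ten-channel
    kinematic feature set with derived angular accelerations; tensorization
    with linear resampling; a compact deep-learning model zoo (1D
    convolutional, recurrent and temporal convolutional families, single-view,
    early-fusion and dual-encoder late-fusion variants) trained with AdamW and
    cosine annealing; participant-stratified cross-validation with
    imbalance-aware metrics; and frequency-based per-participant risk scoring
    with threshold analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
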