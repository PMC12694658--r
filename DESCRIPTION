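Package: lidarousal
Title: Non-Contact Estimation of Electrodermal Arousal from LiDAR Reflection Intensity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating an electrodermal-activity (EDA) derived
    arousal factor from a single-channel LiDAR reflection-intensity time
    series. Provides a seeded multi-subject simulator of stimulus-locked skin
    conductance recordings with a coupled LiDAR channel, signal cleaning
    (zero-phase low-pass filtering, detrending, phasic/tonic decomposition,
    per-participant z-normalization), a rank-percentile arousal statistic
    with k-class discretization, feature-based and sequence-based
    classification and regression models, and evaluation under random-split
    and leave-one-subject-out validation with chance-corrected accuracy and
    Bland-Altman agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    ranger,
    xgboost,
    nnet,
    class,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
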