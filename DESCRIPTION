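Package: hydrowear
Title: Hydration Monitoring from Multi-Sensor Wearable Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate the time since a person last drank water from
    wrist-worn multi-sensor recordings (accelerometer, magnetometer,
    gyroscope, galvanic skin response, photoplethysmography, temperature and
    barometric pressure). Provides a synthetic cohort generator with a known
    latent dehydration link, signal preprocessing (out-of-range clipping,
    vector magnitudes, cumulative motion-jerk features, one-minute
    aggregation), a motion-adaptive PPG beat-detection pipeline (inter-beat
    interval, heart rate, breathing rate, RMSSD with last-value imputation),
    two engineered feature sets with multicollinearity diagnostics, and a
    regression benchmark harness with a transfer-learning personalization
    protocol evaluated on leave-one-subject-out splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    ranger,
    e1071,
    glmnet,
    nnet,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
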