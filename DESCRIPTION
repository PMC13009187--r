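Package: adwear
Title: Detecting Autonomic Dysreflexia Episodes from Multimodal Wearable Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting autonomic dysreflexia (AD) episodes in people with
    spinal cord injury from multimodal wearable recordings (ECG, PPG, bioimpedance-derived
    electrodermal activity, temperature, heart rate and respiratory rate). Provides
    objective AD labeling from sparse cuff blood-pressure readings via shape-preserving
    monotone cubic interpolation, modality-specific signal conditioning and beat
    segmentation, sliding-window feature extraction (heart-rate variability, pulse-wave
    morphology, electrodermal and thermal descriptors), shadow-feature selection driven
    by standardized TreeSHAP importances, a modality- and device-partitioned weak-learner
    ensemble with k-threshold voting and stacked aggregation, leave-one-subject-out
    evaluation under class imbalance, and a synthetic cohort generator emulating
    urodynamic-study sessions so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    Matrix,
    xgboost,
    randomForest,
    e1071,
    MASS,
    class,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse,
    yaml,
    pROC
Config/testthat/edition: 3
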