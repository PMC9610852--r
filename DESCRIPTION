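Package: vigilwave
Title: Cardiorespiratory Vigilance-Attention Analysis from Multichannel
    Near-Field RF Baseband Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, seeded analysis pipeline for detecting
    vigilance-attention versus relaxed-inattention states from
    cardiorespiratory waveforms captured by a four-channel near-field
    radio-frequency sensor (thorax/abdomen x amplitude/phase). Provides a
    synthetic session generator with ground truth (quasi-periodic
    respiration with end-expiratory pauses, heartbeat with second harmonic
    and LF/RSA inter-beat variability, channel mixing, and a clock-task
    responder model); zero-phase Butterworth/Kaiser-FIR vital-sign
    extraction with periodogram SNR channel selection; moving-average-curve
    peak detection, second-harmonic inter-beat intervals, and a refined
    inspire-begin search; sliding-epoch heart-rate-variability and
    respiratory-waveform-variability features; pooled cross-validated,
    leave-one-subject-out and personalized classification protocols (kNN,
    SVM, QDA, boosted and bagged trees); and vigilance-task response
    statistics (probability of correct response, event-locked heart-rate
    ratios, attention-level timelines, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    class,
    MASS,
    e1071,
    randomForest,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
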