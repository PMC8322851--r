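Package: femgfci
Title: Facial-EMG Face-Computer Interface Pipeline with Closed-Loop Robotic-Arm Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and testing a facial surface-electromyography
    (fEMG) intent-recognition pipeline without any recording hardware: a seeded
    synthetic fEMG generator emulating a six-movement facial protocol with
    channel cross-talk, causal notch plus Butterworth band-pass preprocessing
    with a streaming-safe filter state, sliding-window segmentation, eight
    time-domain window features (MAV, RMS, MC, MAC, MAX, ZC, VAR and order-3
    autoregressive coefficients), a twelve-classifier cross-validation harness
    with single-feature ranking and sequential feature-reduction, a two-stage
    finite-state intent decoder with debouncing and audio-broadcast events, and
    a Cartesian point-model robotic-arm simulator that closes the loop on a
    three-stage drinking task.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    nnet,
    rpart,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
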