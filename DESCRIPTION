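Package: emgpr
Title: Pattern-Recognition Myoelectric Control for Coupled Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pattern-recognition myoelectric prosthesis control
    when surface EMG channels are coupled, as after targeted muscle
    reinnervation (TMR). Implements overlapped-window time-domain feature
    extraction (mean absolute value, waveform length, zero crossings,
    slope-sign changes), a regularized Bayes-decision linear discriminant
    classifier, and decision-stream post-processing by majority vote or
    per-motion MAV threshold switches that gate transient-state
    misclassifications. Includes a synthetic coupled-sEMG simulator with
    annotated motion schedules, the training-session labeling protocol,
    rehabilitation MAV-grid analysis, decision-stream evaluation metrics,
    and ARAT score arithmetic, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
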