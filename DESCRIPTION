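Package: capmotion
Title: Forearm Motion Recognition from Noncontact Capacitive Sensing Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An offline analysis pipeline for recognizing forearm motion
    patterns from multichannel capacitance signals that track muscle
    deformation, with inertial (Euler-angle) signals used to label motion
    transitions automatically. Provides a synthetic trial generator with
    ground-truth transition boundaries, zero-phase Butterworth low-pass
    filtering, sliding-window time-domain features (mean, standard
    deviation, maximum, normalized slope), a quadratic discriminant
    classifier implemented from its Gaussian generative definition, and an
    evaluation harness with trial-wise cross-validation schemes, confusion
    matrices, and transition prediction-time metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
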