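Package: swayucm
Title: Uncontrolled-Manifold Analysis of Postural Sway Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes multi-joint quiet-standing kinematics into
    task-equivalent and task-relevant components with respect to postural
    task variables (centre-of-mass position, head position, trunk and head
    orientation) using the uncontrolled-manifold (UCM) approach on a planar
    six-joint sagittal chain model.  Provides a covariation-by-randomization
    surrogate test, time-lagged squared-autocorrelation persistence profiles
    of the variability components, a minimal-intervention sway simulator
    with separate correction time constants parallel and orthogonal to the
    task manifold, and an end-to-end study pipeline with log/atanh
    transforms, one-sample and paired t tests and Holm-corrected decisions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
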