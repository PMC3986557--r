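Package: gazecal
Title: Calibration Methods for Mobile Gaze Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates a mobile user's point of regard on a planar display
    from head-mounted eye-tracker and body-motion-tracker streams. Implements
    two calibration approaches: a geometric pipeline that chains a rigid
    head-to-eye transform, a linear pupil-to-eye-rotation model and a planar
    screen model to intersect the gaze ray with the display, calibrated by
    bounded derivative-free cost minimization; and a regression approach
    using per-axis Gaussian processes with an automatic relevance
    determination kernel, fitted by marginal-likelihood maximization, that
    map the eight-dimensional head-pose and pupil input directly to screen
    coordinates with predictive confidence bounds. Includes a synthetic
    session simulator emulating dynamic-pursuit and static-grid stimulus
    protocols under three user-mobility conditions, and an evaluation
    harness with angular-error metrics, a calibration/validation coverage
    overlap statistic, and confidence-based sample rejection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
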