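Package: okncs
Title: Automated Contrast-Sensitivity Measurement from Optokinetic Nystagmus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automated, eye-movement-based measurement of motion
    contrast sensitivity. Implements velocity-threshold detection of
    optokinetic nystagmus (OKN) quick phases and slow phases from binocular
    gaze recordings, both as a post-hoc (offline, full sampling rate)
    analysis and as a causal frame-by-frame (live) detector that can abort a
    trial as soon as a robust OKN response is seen. A QUEST+ Bayesian
    adaptive staircase selects stimulus contrast from detection outcomes,
    cumulative-Weibull psychometric fitting converts outcome tables into
    contrast thresholds and sensitivities, and a log-parabola model fits the
    contrast-sensitivity function across spatial frequencies. A seeded
    simulator generates labelled saw-tooth OKN and fixation gaze traces and
    psychometrically governed virtual observers, so the entire closed loop
    runs and is validated without eye-tracking hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
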