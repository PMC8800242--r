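Package: elbowrom
Title: Elbow Range-of-Motion Measurement with Electromagnetic Sensor Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes elbow flexion-extension angles from pose streams of
    bone-fixed electromagnetic sensors: stylus digitization of five bony
    landmarks, anatomical frame construction for the upper arm and forearm,
    flexion-angle time series, detection of held (plateau) phases, and the
    method-comparison statistics used to validate such systems (Pearson
    correlation, Bland-Altman limits of agreement, intraclass correlation
    coefficients with F-based confidence intervals). A seeded trial
    simulator emulates the tracking hardware, examiner hold variability,
    digitization error, an in-vivo soft-tissue artifact, and a radiographic
    reference, so the whole pipeline can be exercised end to end without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
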