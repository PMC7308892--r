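Package: oximetry
Title: Two-Wavelength Ear Photoplethysmography Processing, Calibration and
    Accuracy Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and offline analysis of two-wavelength (red/infrared)
    photoplethysmography for pulse oximetry. Generates synthetic subject
    cohorts with ground-truth oxygen-saturation trajectories, activity
    schedules, motion artefacts and noisy reference devices; processes raw
    recordings into per-window ratio-of-signals (ROS) and signal-quality
    estimates via ambient-light correction, zero-phase band-pass filtering,
    beat detection and cardiac-gated ensemble averaging; fits the linear
    ROS-to-SpO2 calibration with leave-one-out cross-fitting across
    subjects; and evaluates accuracy against continuous and arterial
    blood-gas references with bias, precision, A_RMS, Pearson correlation,
    Bland-Altman limits and activity-stratified rejection accounting in the
    style of ISO 80601-2-61 pulse-oximeter validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
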