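Package: ctiq
Title: Image-Quality Evaluation for Dose-Reduced Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for objective and observer-based image-quality
    evaluation of chest CT reconstructions compared at different dose
    levels. Implements anatomical-image power-spectrum estimation with
    ROI mirroring and radial averaging, circular-ROI contrast-to-noise
    ratio with paired-difference statistics, perpendicular line
    profiles, DLP-based effective-dose accounting, and visual grading
    characteristics (VGC) analysis of paired ordinal ratings with
    fixed-reader and random-reader bootstrap confidence intervals. A
    synthetic module generates phantom image stacks with controllable
    noise power spectra and edge enhancement, and simulates
    multi-reader paired ordinal ratings from a latent threshold model,
    so the full pipeline can be exercised and validated without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
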