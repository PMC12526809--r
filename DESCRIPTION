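Package: posturehrv
Title: Sleep-Posture Classification and Posture-Resolved Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for nocturnal Holter recordings with a built-in
    triaxial accelerometer. Classifies sleep posture (supine, right lateral,
    left lateral, prone) from the low-passed gravity vector in 30 s epochs,
    computes time-domain heart rate variability (HR, SDRR) and complex-
    demodulation frequency-domain indices (VLF/LF/HF amplitude, instantaneous
    HF frequency, LF/HF), the HF spectral power concentration index (Hsi),
    and screens for sleep apnea via cyclic variation in heart rate (CVHR),
    then aggregates indices per posture, applies nighttime eligibility rules,
    and stratifies cohorts by age decade and sex with repeated-measures ANOVA
    and eta-squared effect sizes. Includes a synthetic-data generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
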