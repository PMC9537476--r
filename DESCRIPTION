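Package: hifucea
Title: Cost-Effectiveness Modelling of MR-HIFU versus Radiotherapy for
    Painful Bone Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Early health-economic evaluation of Magnetic Resonance guided
    High Intensity Focused Ultrasound (MR-HIFU) as a treatment option for
    painful bone metastases, compared against external-beam radiotherapy
    from a statutory-health-insurance perspective. Implements a
    monthly-cycle state-transition model with a deterministic cohort
    (expectation) engine and an equivalent patient-level microsimulation
    with common random numbers, incremental cost-effectiveness analysis
    (cost per QALY and per month of pain response), one-way deterministic
    and structural sensitivity analyses, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and
    value-of-information estimation (EVPI and regression-based EVPPI).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
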