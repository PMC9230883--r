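Package: accprof
Title: Total-Error Method Validation with Accuracy Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validation of quantitative analytical methods by the total-error
    (accuracy-profile) approach: candidate calibration response functions with
    inverse prediction, per-level bias and variance components from one-way
    random-effects ANOVA, beta-expectation tolerance intervals, and
    LLOQ/ULOQ decisions against acceptance limits. Includes matrix-effect
    assessment from calibration-slope ratios, chromatographic system
    suitability metrics (theoretical plates, tailing factor, signal-to-noise),
    cumulative-release computation for two-stage dissolution tests with
    withdrawal/replacement correction, and synthetic-data generators that
    emulate a hierarchical series/replicate validation design, exponentially
    modified Gaussian chromatograms, and first-order dissolution runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
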