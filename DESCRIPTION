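Package: mrcpdetect
Title: Movement-Intention Detection from Movement-Related Cortical Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline detection of movement intention from single-trial
    movement-related cortical potentials (MRCPs) in cue-based EEG recordings.
    Provides a seeded generator of synthetic EEG/force recordings, Laplacian
    surrogate-channel preprocessing with zero-phase Butterworth filtering,
    force-based movement-onset detection and epoch extraction, temporal and
    spectral (Welch band-power) feature sets, linear discriminant analysis and
    template-matching detectors, a nested five-fold test procedure with
    detection-error, sensitivity and specificity metrics, Friedman-test method
    comparison across subjects, and a three-class Fisher discriminant
    projection for feature-space visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
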