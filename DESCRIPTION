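Package: nirsbci
Title: Personalized Multi-Class Mental-Task Classification for fNIRS Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete offline analysis pipeline for prefrontal functional
    near-infrared spectroscopy (fNIRS) brain-computer interfaces with
    personalized task selection. Converts raw dual-wavelength optical
    intensities to hemoglobin concentration changes via the modified
    Beer-Lambert law, applies Chebyshev low-pass filtering and trial
    segmentation, extracts temporal slope features and spatial features based
    on discrete orthonormal Tchebichef image moments of interpolated
    topographic maps, selects features with the fast correlation-based filter
    (FCBF), and classifies mental tasks with a one-vs-one ensemble of bagged
    linear discriminant classifiers combined by majority voting. Includes
    exhaustive task-subset personalization under repeated stratified
    cross-validation, binomial chance-level confidence limits, correlation of
    accuracy with user characteristics, and a synthetic-data generator
    emulating a multi-session block protocol with physiological noise so the
    full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
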