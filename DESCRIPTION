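Package: nirstensor
Title: Tensor Decomposition Analysis of fNIRS Hemodynamic Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers time-of-interest (TOI) windows and region-of-interest
    (ROI) channel sets in which functional near-infrared spectroscopy (fNIRS)
    hemodynamic responses differ across the conditions of a 2x2 design.
    Trial-averaged oxygenated-hemoglobin epochs are assembled into
    per-hemisphere tensors (time x frequency x channel x subject via the
    short-time Fourier transform, or time x channel x subject), decomposed by
    nonnegative canonical polyadic decomposition (alternating least squares
    with HALS updates) and orthogonal Tucker decomposition (higher-order
    orthogonal iteration), screened for physiological relevance with
    cross-run consensus, and tested component-wise with factorial ANOVA on
    the subject-mode scores. Significant components are summed into temporal,
    spatial and spectral profiles from which TOI and ROI are read off and
    followed up with JZS Bayes-factor contrasts. A synthetic multi-subject
    generator with planted effects and a grand-averaging baseline analysis
    are included for validation and head-to-head comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    yaml,
    jsonlite,
    car,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
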