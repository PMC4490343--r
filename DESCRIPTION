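Package: cardioflow
Title: Optical-Flow and Machine-Learning Screening of Cardiomyocyte Contractility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies drug effects on beating cardiomyocytes from label-free
    brightfield video. Dense optical flow converts time-lapse image stacks into
    motion-vector fields, principal component analysis collapses the fields into
    a one-dimensional contractile profile, per-beat shape parameters are
    extracted, and a radial-basis support vector machine classifier turns
    baseline-versus-condition feature tables into a screening accuracy index.
    Also provides the companion fluorescence calcium-transient pipeline
    (transient detection, photobleach detrending, CTD90/SR90 metrics) and the
    repeated-measures statistics (Mauchly sphericity test, Greenhouse-Geisser
    corrected ANOVA, Dunnett many-to-one comparisons) used to evaluate it, plus
    a synthetic-data generator producing videos, traces and multi-well cohorts
    with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    mvtnorm,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
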