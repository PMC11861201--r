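Package: facemotor
Title: Facial Muscle Synergies and Keypoint Displacement Estimation from
    Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing facial surface electromyography (sEMG)
    during the execution of basic facial expressions. Implements the full
    envelope-processing pipeline (band-pass filtering, rectification,
    maximum-voluntary-contraction normalisation, low-pass enveloping,
    transition trimming and trial reordering), muscle-synergy extraction by
    non-negative matrix factorisation with variance-accounted-for rank
    selection, sliding-window feature extraction and random-forest
    expression classification, and a family of keypoint-displacement
    estimators built on a skin-musculoskeletal spring-equilibrium model
    (SMSM), a multivariate linear regression model (LRM) and their hybrid
    (SMSM-LRM), fitted by the Adam optimiser. A seeded synthetic-data
    generator emulates the statistical structure of multichannel facial
    sEMG and keypoint trajectories so that every stage is testable without
    human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    ranger,
    pROC,
    jsonlite,
    data.table,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
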