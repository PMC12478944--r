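Package: pigcall
Title: Recognition of Porcine Abnormal Sounds with Confidence-Weighted Multi-SVDD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting and classifying abnormal pig vocalisations
    (coughs and screams) in short farm recordings. Implements an energy-based
    activity gate, spectral-subtraction denoising with IMCRA noise-power
    tracking, MFCC and delta-MFCC feature extraction, and a confidence-weighted
    Support Vector Data Description (SVDD) classifier in which subtractive-
    clustering densities down-weight likely mislabeled training frames. Two
    one-class hyperspheres (cough, scream) are fused by a decision table and
    frame-level majority voting; hyperparameters can be tuned by particle swarm
    optimisation. A seeded synthetic-sound generator provides labeled fixtures
    so the full pipeline is testable without farm recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
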