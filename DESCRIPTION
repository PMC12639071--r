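Package: gradmodes
Title: Structure-Function Analysis of Neurodegeneration via Activity
    Gradients and Oscillator Eigenmodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking regional gray-matter atrophy to brain-wide
    functional connectivity through low-dimensional activity gradients.
    Implements normative W-score atrophy mapping with location-scale scanner
    harmonization, PCA-based gradient derivation and projection of regional
    BOLD timeseries, reconstruction of functional connectivity from gradient
    covariance, partial least squares regression linking atrophy to
    connectivity edges, a coupled damped harmonic oscillator model of
    gradient dynamics with companion-matrix eigenmode analysis (cumulative
    amplitudes and weighted circular phase angles), and generalized additive
    brain-behavior models with false discovery rate control. A synthetic
    cohort generator with planted atrophy components, atrophy-modulated
    oscillator dynamics, and cognition provides ground truth for testing
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    mgcv,
    glmnet,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
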