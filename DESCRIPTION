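Package: cdinvert
Title: Hybrid Neural and Iterative Phase Retrieval for Coherent Diffraction Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inverting single-particle coherent X-ray diffraction
    patterns into complex (amplitude + phase) real-space images. Provides a
    synthetic strong-phase particle simulator (superellipsoid shapes with
    Gaussian-correlated interior phase), a central-slice diffraction forward
    model, classical iterative phase retrieval (error reduction, hybrid
    input-output, shrink-wrap support refinement), a two-branch
    encoder-decoder convolutional network that predicts amplitude and phase
    directly from a diffraction pattern, a nearest-neighbour-search baseline,
    and a hybrid scheme in which network predictions seed iterative
    refinement. Includes chi-squared reconstruction-error metrics, Gamma
    error-histogram summaries, trivial-ambiguity alignment and 2D phase
    unwrapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    generics,
    tibble,
    rlang,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
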