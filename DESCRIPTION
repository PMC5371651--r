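Package: pcbcdim
Title: Hierarchical Predictive Coding (PC/BC-DIM) for Visual Object Recognition
Version: 0.1.0
Authors@R:
    person("pcbcdim", "maintainers", email = "pcbcdim@example.org", role = c("aut", "cre"))
Description: Implements the PC/BC-DIM predictive-coding network (predictive
    coding / biased competition with divisive input modulation) for visual
    object recognition: iterative explaining-away inference over learned
    feature dictionaries in both matrix and convolutional form, ON/OFF
    local-contrast preprocessing, ZMNCC-based agglomerative dictionary
    learning from whole images or Harris keypoint patches, a two-stage
    hierarchy whose second stage votes for object classes or object
    locations and scales, generalized-Hough-style detection with population
    vector decoding, and precision-recall / equal-error-rate evaluation.
    Ships a seedable synthetic glyph and scene generator so the full
    pipeline is exercisable without external datasets, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
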