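Package: scnet
Title: Structural Covariance Network Analysis of Cortical Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds group-level structural covariance networks (SCN) from
    regional cortical thickness: covariate-adjusted Pearson correlation
    matrices, density thresholding across a sweep, global and nodal
    graph-theoretic metrics (clustering, path length, efficiency,
    betweenness, degree) with degree-preserving random-network
    normalization (gamma, lambda, sigma), and group comparison through
    permutation tests on area-under-the-curve statistics with false
    discovery rate control. Ships a synthetic two-group cohort generator
    with known covariate effects and modular covariance for validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
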