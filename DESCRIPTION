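Package: tripletembed
Title: Structure-Preserving Dimensionality Reduction with Siamese
    Triplet Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Parametric non-linear dimensionality reduction for single-cell
    expression data (mass cytometry and scRNA-seq) and other large numeric
    tables.  A weight-shared siamese network of SELU dense layers is trained
    on triplets mined from an approximate k-nearest-neighbour graph, using a
    triplet loss whose hinge subtracts the minimum of the anchor-negative and
    positive-negative distances.  The fitted model is a parametric map, so
    new observations are embedded without refitting.  Includes the matching
    evaluation protocol (centroid-distance Mantel tests over repeated
    subsamples, run-to-run stability, out-of-sample classification) and
    generators for the Smiley, Cassini and uniform-noise benchmark datasets
    with their nine-dimensional polynomial lifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    irlba,
    jsonlite,
    Matrix,
    methods,
    purrr,
    ranger,
    Rcpp,
    RcppAnnoy,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
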