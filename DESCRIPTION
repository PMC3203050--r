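Package: navbasis
Title: Spatial Basis Functions and Geodesic Generalization for
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Simulates temporal-difference (TD(lambda)) value learning in
    discrete gridworld navigation tasks over biologically inspired spatial
    basis sets: a tabular one-hot code, multiscale Gaussian place-cell-like
    fields, and hexagonal three-cosine grid-cell-like fields.  Each basis
    family can be evaluated in ordinary Euclidean coordinates or in geodesic
    coordinates obtained by embedding obstacle-respecting shortest-path
    distances with Sammon-stress multidimensional scaling, so that firing
    fields generalize along paths rather than across walls.  Includes
    archetypal maze layouts, dynamic-programming ground-truth values,
    learning-rate calibration, learning-curve experiments, value-bleed
    metrics at barriers, and firing-field demonstrations (corridor place
    fields, wall-bisection field disappearance, barrier-induced field gain,
    hairpin grid distortion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
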