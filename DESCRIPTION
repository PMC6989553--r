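Package: coronet
Title: Morphometry, Hemodynamics and Perfusion Territories of Coronary
    Arterial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing and simulating coronary arterial
    networks. Provides a graph data model for vascular networks (node
    classification, arcade loop counting, mother/daughter orientation),
    bifurcation morphometry (daughter symmetry, area growth, diameter
    scaling exponents, allometric power laws), stochastic generation of
    arterial trees down to the capillary domain from per-diameter-class
    branching statistics, steady-state Poiseuille-Kirchhoff network
    hemodynamics with diameter-dependent in vivo blood viscosity,
    distal-conductance imputation (stochastic and deterministic) with
    variability analysis, and Voronoi-based myocardial
    perfusion-territory analysis on voxel grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
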