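Package: netrent
Title: Rentian Scaling, Fractal Dimension and Wiring Economy of Spatially
    Embedded Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topophysical analysis of information-processing networks that are
    embedded in two- or three-dimensional Euclidean space, such as neuronal
    connectomes and integrated circuits. Estimates the topological Rent
    exponent by recursive minimum-cut bipartitioning (Fiduccia-Mattheyses) and
    the fractal topological dimension, the physical Rent exponent from randomly
    placed Euclidean boxes with robust regression, hierarchical modularity with
    significance testing against degree-preserving and pure-random null models,
    wiring-cost statistics (node spacing, normalised mean connection distance,
    the cost-efficiency coefficient kappa) and minimally rewired baselines, and
    the conversion between Rent exponents and the gray/white-matter allometric
    scaling exponent. Includes generators for lattices, hierarchical modular
    spatial networks and power-law scatters so every estimator is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
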