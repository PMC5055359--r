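Package: purkinet
Title: Morphometry and Complex-Network Analysis of Distal Cardiac
    Purkinje Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative characterisation of the distal cardiac Purkinje
    network at cellular scale. Provides 3D cell-mesh morphometry (triangle-sum
    surface area, divergence-theorem volume, principal-axis dimensions),
    reconstruction of spatially embedded centreline graphs from labelled 3D
    landmarks with branch-length and furcation-angle extraction, weighted and
    binary complex-network metrics (global and local efficiency, betweenness,
    degree assortativity, characteristic path length), degree-preserving random
    and lattice null ensembles with a small-world connectivity test, circular
    statistics and one-way ANOVA for angle populations, and a synthetic-data
    generator producing Purkinje-like tree/plexus networks and parametric cell
    meshes so the whole pipeline is testable without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
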