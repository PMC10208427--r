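Package: epitess
Title: Geometric and Network Analysis of Epithelial Tessellations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the organization of packed epithelial
    monolayers from segmented label images: polygon-class (sidedness)
    distributions and cell-area morphometry, automated quantification of
    border interdigitation (peak counts and a redundancy index), conversion
    of segmentations into cell-contact graphs with exact graphlet orbit
    counting (2-5 node graphlets, 73 orbits), and the graphlet degree
    distribution agreement distance (GDD) against hexagonal, random-Voronoi
    and relaxed-Voronoi reference patterns.  Includes a synthetic
    tessellation generator (random Voronoi, Lloyd/centroidal-Voronoi
    iteration paths with optional seed noise, hexagonal lattices, and
    wavy-border variants with known ground truth) for validation, a
    watershed segmentation stage for boundary-stained images, placement of
    samples on a noisy centroidal-Voronoi (CVTn) reference scale with
    randomization significance, and MANOVA across sample groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    MASS,
    png,
    tiff,
    EBImage,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
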