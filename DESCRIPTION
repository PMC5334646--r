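Package: spheroidr
Title: Multiscale Image Analysis of Nuclei-Stained Multicellular Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-analysis pipeline for three-dimensional light-sheet
    stacks of optically cleared, nuclei-stained multicellular spheroids.
    Provides isotropic pre-processing of anisotropic stacks, nuclei
    segmentation by local adaptive thresholding, multiscale
    Laplacian-of-Gaussian marker detection and marker-controlled immersion
    watershed, per-nucleus morphological and intensity features, alpha-shape
    reconstruction of the spheroid surface with normalized depth (NDS),
    proximity and Delaunay cell graphs for local cell density, radial and
    region-wise density analysis, a random-cell-position null model, and a
    centroid-matching evaluation framework, together with a synthetic phantom
    generator that supplies exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    cluster,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
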