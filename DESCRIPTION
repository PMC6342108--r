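Package: resgen
Title: Resistance-Surface Optimization and Microgeographic Landscape Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based landscape genetics at microgeographic scale:
    microsatellite diversity statistics, Hardy-Weinberg exact tests, Weir-Cockerham
    FST, proportion-of-shared-alleles (Dps) distances, maximum-likelihood relatedness
    classification and first-order pruning; K-means/BIC cluster scans and discriminant
    analysis of principal components; environmental surface construction (NDVI,
    ordinary kriging, binary reclassification) on matrix-backed grids with ESRI ASCII
    I/O; monomolecular and Ricker resistance transformations with commute-time
    (circuit-theory) distances on the 8-neighbour raster graph; maximum-likelihood
    population-effects (MLPE) mixed models of pairwise genetic distance with AICc
    model selection; genetic-algorithm optimization of transformation parameters with
    Spearman pre-filtering and bootstrap model selection; Mantel tests and
    correlograms; kernel utilization distributions and home ranges from telemetry;
    and a synthetic-data generator emulating all required inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
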