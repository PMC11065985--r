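Package: vasctree
Title: Morphometric Analysis of Cast Vascular Networks in 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of radiopaque-cast vascular networks
    imaged by volumetric X-ray modalities (clinical CT, digital volume
    tomography, micro-CT, synchrotron phase-contrast imaging). Provides
    volume input/output with physical voxel spacing, median filtering and
    density-based region growing, hole filling, surface-mesh voxelization,
    sphere-based local vessel diameter maps (maximal inscribed spheres)
    with volume-by-diameter histograms, topology-preserving skeletonization
    and reduction to a vessel-segment graph, the three classic branching
    classifications (generation, Horsfield order, Strahler order),
    Gaussian-mixture clustering of vessel segments with BIC model selection
    over covariance parameterizations, Davies-Bouldin and Dunn cluster
    validity indices, label back-mapping onto the 3D volume, and a
    synthetic vascular phantom generator with full ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
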