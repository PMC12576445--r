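Package: canopy3d
Title: Tree-Level Canopy and Floral Trait Analysis from Multi-Source Orchard Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis chain that turns multi-source orchard point clouds
    (LiDAR-like clouds carrying per-point intensity and drone-like
    photogrammetric clouds carrying colour) into tree-level traits. Stages
    cover statistical outlier removal, cloth-style ground filtering and
    canopy height models, automated tree segmentation and grid positioning,
    Laplacian-contraction skeleton extraction with coarse (feature-based)
    plus fine (iterative closest point) rigid registration for cross-source
    fusion, graph-theoretic and intensity-based pruning of support
    structures with voxel gap filling and branch counting, convex-hull
    crown morphometrics, and density-based blossom cluster detection and
    classification. A synthetic-orchard generator provides ground-truthed
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RANN,
    FNN,
    interp,
    igraph,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
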