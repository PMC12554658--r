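Package: planthull
Title: Plant-Type Identification from 3D Point Clouds via Multi-View
    Silhouette Convex Hulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the canopy architecture class of single plants
    (cylinder vs tower type, as used in cotton phenotyping) from colored 3D
    point clouds. Provides ASCII PLY/XYZRGB input and output, point-cloud
    preprocessing (principal-axis coordinate correction, statistical outlier
    removal, color conditional filtering, voxel-grid down-sampling, plant
    height/width extraction), rotational multi-view 2D silhouette projection,
    a from-scratch divide-and-conquer quickhull with left/right silhouette
    chain decomposition and Douglas-Peucker chain simplification, the
    corner-change-rate curvature statistic with interval-based majority
    classification, an evaluation toolkit (confusion metrics, RMSE, Fleiss
    and Cohen kappa, Welch t-test, seeded k-fold cross-validation), and a
    synthetic surface-of-revolution plant-cloud generator with known ground
    truth for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
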