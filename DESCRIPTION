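Package: caplidar
Title: Canopy Features and Effective Leaf Area Index from Row-Crop LiDAR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for estimating effective leaf area
    index (LAI) of row crops such as sorghum and maize from discrete-return
    LiDAR point clouds. Reads LAS/CSV/PLY point clouds and GeoJSON plot
    polygons, builds a minimum-grid bare-earth terrain model, normalizes
    point heights and applies the 10-cm ground rule, and extracts eight
    per-plot canopy features: the laser penetration index (LPI), height
    mean, standard deviation, skewness and third quartile, the vertical
    complexity index (VCI), convex-hull canopy volume, and the Clusters'
    Area Plane (CAP) - the summed area of region-grown point clusters in a
    thin horizontal slice at a height quantile. Fits and evaluates stepwise
    multiple linear regression, partial least squares regression, and
    support vector regression models mapping features to ground-reference
    effective LAI under a variety-level 75/25 split with 10-fold
    cross-validation, and ranks features by a leave-one-out weight
    procedure. Includes a Beer-Lambert synthetic row-canopy generator so
    the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    FNN,
    generics,
    ggplot2,
    jsonlite,
    mixOmics,
    purrr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
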