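Package: canopystrat
Title: Canopy Stratification and Occlusion Modelling for Forest LiDAR Point Clouds
Version: 0.1.0
Authors@R:
    person("Forest", "Informatics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to stratify airborne laser scanning (LiDAR) point clouds of
    closed-canopy forests into vertical canopy layers, estimate the fraction of
    points returned from each layer, fit a logarithmic-series occlusion model to
    those fractions, and derive the point-cloud density required to segment
    trees in a given canopy layer. Includes pulse-aware point-cloud decimation,
    a simple surface-based individual-tree segmenter, Hungarian-assignment
    matching of detected trees against stem maps with recall/precision/F-score,
    and a synthetic multi-layer forest LiDAR simulator with per-point truth
    labels for end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
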