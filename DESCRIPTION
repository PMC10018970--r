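Package: vascumorph
Title: Quantitative 3D Vascular Architecture Analysis for Cleared-Tissue Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify three-dimensional vascular architecture from
    light-sheet fluorescence microscopy volumes of labelled vasculature:
    volumetric median filtering, thresholding and fragment filtering of vessel
    masks, topology-preserving skeletonization and centerline graph tracing
    with per-segment morphometrics (length, diameter, straightness,
    orientation), anisotropic Euclidean distance transforms of the
    extravascular space with the RM10 heterogeneity statistic, and
    highest-density-region areas of two-dimensional kernel density estimates
    of diameter versus straightness. A synthetic vasculature generator
    produces organ-archetype (parallel fibers, random arcs, planar meshes)
    and tumor-archetype networks with exact ground truth, rasterized into
    image volumes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
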