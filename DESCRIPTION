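Package: rootkin
Title: Single-Cell Nucleus Tracking and Morphokinetic Analysis of Root Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infrastructure for 4D (3D + time) single-cell nucleus tracking and
    morphokinetic analysis of growing plant roots. Includes a root-growth
    simulator with zone-dependent axial velocity, meristem skewing (rigid
    rotation), cell division and delayed reporter activation; 3D nucleus
    detection in voxel stacks; gap-closing track linking with constant-velocity
    prediction and Hungarian assignment; per-cell kinematics (velocity,
    acceleration, displacement-squared, instantaneous angle) and the
    coordinated-motility mean-cosine statistic; zone-resolved spatiotemporal
    maps and skewing rotation fits; reporter quantification (region-of-interest
    intensity series, ratiometric reporters, onset timing); and cohort-level
    feature matrices with hierarchical clustering of experimental lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
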