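Package: guidefit
Title: Accuracy Verification of CT-Derived Dental Guide Models Against
    Optical Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring the accuracy lost when transferring
    CT-based dental implant planning to physical surgical guides. Provides
    threshold segmentation of CT volumes with marching-cubes isosurface
    extraction, rigid alignment of the CT-derived model to a gold-standard
    optical-scan mesh (landmark SVD followed by trimmed iterative
    closest-point refinement), full-field signed point-to-surface deviation
    statistics restricted to mating-surface regions of interest, and
    calibration of the segmentation threshold by minimising the absolute
    mean signed deviation against the optical reference. A synthetic
    dental-arch phantom generator (CT-like voxelisation with partial-volume
    blur and noise, plus a noisy optical-scan analogue in a known pose)
    makes every stage verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
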