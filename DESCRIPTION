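Package: axomorph
Title: Automated 3D Segmentation and Morphometry of Axons in Serial
    Block-Face Electron Microscopy Volumes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segments white-matter ultrastructure in serial block-face
    scanning electron microscopy (SBEM) volumes and quantifies the 3D
    morphology of myelinated axons. Segmentation combines bounded volume
    growing behind dilated Canny edge barriers with SLIC supervoxel
    refinement and rule-based annotation of myelin, axons, mitochondria,
    vacuoles and cells. Morphometry extracts sub-voxel axonal centrelines
    from eikonal (multi-stencil fast marching) arrival-time maps and
    measures perpendicular cross-sections by moment-matched ellipses.
    Includes segmentation-accuracy metrics with optimal region matching,
    nested ANOVA and variance-component statistics for hierarchical
    measurements, and a synthetic phantom generator with ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
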