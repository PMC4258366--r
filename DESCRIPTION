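Package: hipkin
Title: Single-Plane 3D-to-2D Model-to-Image Registration for Skeletal
    Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks the six degree-of-freedom pose of volumetric bone models
    in single-plane radiographic image sequences by digitally reconstructed
    radiograph (DRR) rendering and image-based registration, and converts the
    tracked poses into clinical pelvic, femoral and hip joint angles.
    Includes a perspective projection model with source calibration from
    fiducials, a ray-casting DRR renderer, normalized cross-correlation and
    exclusive-disjunction similarity metrics with a staged derivative-free
    pose search, anatomical coordinate frames built from the anterior pelvic
    plane and the transepicondylar axis, movement-cycle normalization of
    angle time series, a synthetic phantom generator, and a root-mean-square
    pose-recovery accuracy protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    png,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
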