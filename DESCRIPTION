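Package: cardioDIC
Title: Stereo Digital Image Correlation for Cardiac Surface Biomechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subset-based stereo digital image correlation (DIC) for
    quantifying the motion and deformation of the beating heart surface from
    speckle-patterned grayscale image sequences. Provides a synthetic
    beating-heart image simulator with exact analytic ground truth, a
    subpixel subset tracking engine with incremental ("sum of differentials")
    and fixed-reference accumulation, pinhole stereo calibration and
    triangulation, and the cardiac kinematics layer: displacement components,
    principal strains, tissue velocity with systolic/diastolic characteristic
    points, beat segmentation and stitching, virtual-extensometer fractional
    shortening, and strain/strain-rate traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    signal,
    pracma,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
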