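Package: stitchforge
Title: Desk-Scale Stitching and Alignment of Serial-Section Electron Microscopy Tile Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assembles serial-section electron microscopy tile mosaics from
    point correspondences: per-tile 2D montage stitching by regularized sparse
    least squares, thin-plate-spline lens-distortion estimation from
    high-overlap calibration montages, robust correspondence filtering
    (locally optimized RANSAC with 3-sigma residual trimming), progressive
    per-section 3D alignment (rigid, affine, thin plate spline), automated
    stitching quality control (residuals, seams, gaps, scale MAD, angular
    residuals), regularization-parameter sweeps, chunk fusion with transform
    interpolation, and rendering of flattened sections and MIPmap pyramids.
    A synthetic-data generator produces tile grids, images, and
    correspondences with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
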