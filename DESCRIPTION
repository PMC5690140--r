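Package: tiletrack
Title: Markerless Lung Tumor Tracking on kV Projections by Tile-Shifted
    Normalized Cross-Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-step markerless localization of moving lung tumors on
    kilovoltage projection images. Planning CT volumes are split into
    tumor-free background and tumor-only volumes using the planning
    contour, digitally reconstructed radiographs (DRRs) are computed by
    ray tracing with trilinear interpolation, and each projection is
    matched against the background DRR over a shifted grid of
    non-overlapping tiles scored by normalized cross-correlation. The
    tile whose similarity stays low (the tile holding the tumor) is
    excluded, per-tile linear intensity maps are interpolated bilinearly
    to pixel level, and the transformed DRR is subtracted so the tumor
    emerges in the residual, where it is located by template matching
    against the tumor DRR. Includes a synthetic respiratory torso
    phantom with programmable motion, implanted fiducial markers,
    marker inpainting, CLAHE contrast correction, and tracking-accuracy
    evaluation against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
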