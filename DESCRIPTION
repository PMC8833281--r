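Package: cathrecon
Title: Semiautomatic Catheter Reconstruction in Dual-Contrast MR Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage semiautomatic reconstruction of interstitial
    brachytherapy catheters in paired T1-weighted/T2-weighted MR volumes.
    A patch-based 2D U-net (implemented natively with compiled
    convolution kernels) segments candidate catheter cross-sections on
    each axial slice; deterministic post-processing then refines
    candidates to local intensity extrema, links them slice-to-slice,
    imputes missed ("jumping") catheters from the mean displacement of
    detected ones, and terminates each path from the catheter's physical
    free-length geometry. Includes a synthetic dual-contrast MR phantom
    generator with known ground-truth trajectories, and evaluation of
    reconstructions via dwell positions resampled at 1 mm arc-length
    spacing (mean deviation, thresholded fractions, Dice overlap,
    Hausdorff distance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
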