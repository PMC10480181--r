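Package: stripecor
Title: Self-Supervised Stripe and Artifact Correction for Stitched Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised, per-image correction of tile-shading stripes and
    local artifacts in large stitched fluorescence microscopy mosaics. The
    method samples anomaly patches on stripes and pairs each with its nearest
    stripe-free neighbour (proximity sampling), trains a pair of
    generator/discriminator convolutional networks with least-squares
    adversarial and cycle-consistency losses on those unpaired patches, and
    corrects the whole mosaic by sliding-window inference with feathered
    overlap blending. Includes a parametric simulator of stitched-microscope
    degradations (uniform, non-uniform, grid and oblique tile shading;
    out-of-focus, scanning-fringe and bubble artifacts) over procedurally
    generated tissue-like phantoms, and quality metrics (inverse coefficient
    of variation, intensity profiles, PSNR, SSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
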