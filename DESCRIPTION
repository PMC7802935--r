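Package: frm
Title: Fluorescence Reconstruction Microscopy from Transmitted-Light Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts fluorescence channels (nuclei, cell-cell junctions,
    actin) from transmitted-light micrographs with an image-to-image U-Net
    trained under a mean-squared-error or Pearson-correlation loss. Provides
    paired-TIFF dataset preparation (bit-depth normalization, 256x256 tiling,
    z-normalization, reproducible train/validation/test splits), a from-scratch
    convolutional U-Net with ADADELTA optimization and early stopping,
    correlation-based evaluation metrics (per-image PCC, the feature-filtered
    accuracy score P, segmentation PCC, cytofluorograms, scaled-MAD outlier
    removal), sliding-window stitching of predictions over arbitrarily large
    images and timelapse stacks with border exclusion and cross-platform
    pixel-size correction, downstream biological readouts (nuclei segmentation
    and counting, centroid displacement, junction-based cell-area morphometry,
    line profiles), training-set-size and epoch sweep harnesses, and a
    deterministic synthetic generator of paired phase-contrast-like and
    fluorescence-like scenes with exported ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
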