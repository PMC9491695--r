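Package: hsistain
Title: Label-Free Hyperspectral Virtual Staining of Retinal Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for transforming label-free hyperspectral microscopy
    hypercubes of retinal cross-sections into virtually stained
    histopathology-like images. Provides multi-page TIFF hypercube I/O with a
    wavelength sidecar, lamp-spectrum calibration against spectrometer
    readings, extraction and categorization of calibrated peak-normalized
    spectral signatures of amyloid-beta (Abeta42) and phosphorylated tau
    (pS396-Tau) deposits, similarity and local-weighted-mean control-point
    image registration, principal-component compression of hypercubes to
    three-channel images, paired-patch dataset construction with twelve-fold
    augmentation, a conditional generative adversarial network (U-Net
    generator, patch discriminator, L1 + SSIM-regularized loss) for
    image-to-image translation into DAB or immunofluorescence renderings,
    field-of-view mosaic stitching with overlap seam search, and SSIM/PSNR
    evaluation reports. A synthetic retinal-phantom generator provides
    paired ground truth so the entire workflow can be exercised without
    donor tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
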