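Package: lesionpipe
Title: Dermoscopy Lesion Preprocessing, Feature Extraction and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of dermoscopic skin-lesion images: digital hair
    removal (BlackHat morphology plus diffusion inpainting), rolling-ball
    background correction, spatial denoising filters (non-local means, mean,
    median, Gaussian, conservative smoothing), contrast enhancement (histogram
    equalization, piecewise linear transformation) with quality-metric driven
    selection (PSNR, MAE, SSIM, Dice, histogram distance), Otsu region-of-interest
    segmentation and binary morphology, extraction of 14 geometric and 6 textural
    lesion features, PCA loading-based feature selection, and a compact dense
    neural-network classifier trained with five hand-rolled optimizers
    (SGD, RMSprop, Adam, Adamax, Nadam). A synthetic-data module generates
    dermoscopy-like images with ground-truth lesion and hair masks so the whole
    pipeline is testable without external image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    jsonlite,
    yaml,
    png,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
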