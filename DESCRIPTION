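Package: sonodae
Title: Intensity Inhomogeneity Correction and Stacked Denoising
    Autoencoder Classification for Breast Ultrasound ROIs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for benign/malignant classification of small breast
    ultrasound lesion regions of interest. Implements retrospective
    intensity-inhomogeneity (bias field) correction by alternating a
    fuzzy cell-based foreground/background bipartition with joint
    least-squares fitting of region means and a low-order bivariate
    polynomial surface, and a from-scratch stacked denoising autoencoder
    with tied weights, greedy layer-wise pretraining and a sigmoid
    logistic-regression head trained by full-batch gradient descent.
    Includes a seeded generator of speckle-noise lesion phantoms with
    known bias fields, confusion-matrix evaluation, and a driver for
    side-by-side original-versus-corrected experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
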