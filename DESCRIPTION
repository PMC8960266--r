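Package: ramanld
Title: Chemometrics and Morphometry of Lipid-Droplet Raman Spectra and Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying lipid-droplet metabolism from spontaneous
    Raman spectra and stimulated Raman scattering (SRS) / two-photon
    fluorescence (TPF) microscopy. Implements per-droplet background
    subtraction and normalization of Raman spectra; Kullback-Leibler
    (relative-entropy) ranking of wavenumbers by class-discriminating power;
    Gaussian-Lorentzian (pseudo-Voigt) multi-peak unmixing with fit-error and
    R-squared reporting; ratiometric de novo lipogenesis statistics (C-D and
    C-H band ratios) with balanced two-way ANOVA and two-tailed t-tests; a
    rectifier multilayer-perceptron spectral classifier and PCA to t-SNE
    embedding; and 3D lipid-droplet morphometry (de-striping, segmentation,
    sphericity scoring) plus autofluorescence redox-ratio quantification with
    rolling-ball and sliding-paraboloid background subtraction. A synthetic
    data module generates labelled spectra cohorts and image phantoms with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    minpack.lm,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
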