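Package: stainquant
Title: Quantitative Image Analysis of Histological Stains with
    Nonparametric Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reproducible quantification of trilineage-differentiation
    assays from RGB microscopy: calibration-based illumination correction,
    optical-density color deconvolution with polar-parametrized stain
    vectors and programmatic kernel estimation, local-adaptive and global
    (Otsu) binarization for cell and pellet masks, phase-contrast
    confluency, fluorescence dead-cell counting, histology scoring,
    efficiency-corrected qPCR expression ratios, and exact nonparametric
    repeated-measures statistics (Friedman and Wilcoxon signed-rank) for
    donor-blocked cohorts. Includes a synthetic-microscopy generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
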