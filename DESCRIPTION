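Package: enthesomorph
Title: Quadriceps Enthesis Histomorphometry and Cohort Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-dimensional histomorphometry of the quadriceps
    tendon enthesis and the proximal patella: Laplacian-of-Gaussian
    zero-crossing segmentation of scanned trabecular bone sections, apparent
    bone area and trabecular thickness indices via mean intercept lengths,
    perpendicular thickness measurement of calcified and uncalcified
    fibrocartilage from annotated sections, and a cohort-level statistical
    layer (muscle-volume contributions, ICRS consensus grading,
    lateral/medial ratios, Wilcoxon comparisons, Spearman correlation with
    strength categories). A synthetic-data module generates trabecular
    textures with known ground truth, annotated enthesis sections, and
    rank-correlated donor cohorts via a latent Gaussian copula, so the whole
    pipeline is testable without cadaveric material.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
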