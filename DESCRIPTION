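Package: thyrometab
Title: NMR Metabonomics and Fatty-Acid Analytics for Thyroid Tissue
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for tissue metabonomics by 1D 1H NMR:
    spectral bucketing and normalization, mean-centered PCA, unit-variance
    OPLS-DA with stratified 7-fold cross-validation, CV-ANOVA model
    significance, ROC curves from cross-validated predictions, and
    back-scaled correlation loadings with critical-|r| cutoffs, plus
    downstream GC-FID/MS fatty-acid composition analytics (class roll-ups,
    molar percentages, desaturase indices, group comparisons). A synthetic
    spectrum generator with planted, annotated group effects makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
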