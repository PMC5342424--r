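Package: radiopsp
Title: Radiogenomic Discovery of Pseudoprogression Biomarkers in Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for radiogenomic biomarker discovery in
    glioblastoma pseudoprogression (PsP) versus true tumor progression (TTP).
    Screens differentially expressed genes with Wilcoxon rank-sum tests,
    associates them with longitudinal MRI-derived tumor morphometrics through
    a multi-task longitudinal sparse regression (row-wise group sparsity,
    temporal smoothness and trace-norm regularization, fitted by an
    iteratively reweighted closed-form update), and selects candidate genes
    by a coverage-rate stability criterion over a hyperparameter grid before
    validating them on an independent cohort. Includes tumor-mask
    morphometrics and a synthetic-cohort generator that emulates the
    statistical structure of the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    png,
    RNifti,
    ape,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
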