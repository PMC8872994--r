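Package: mifquant
Title: Multiplex Immunofluorescence Quantification and Longitudinal
    Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative multiplex
    immunofluorescence: linear spectral unmixing of multispectral tissue
    images with an autofluorescence component, DAPI-based nuclear
    segmentation with metric cytoplasm ring expansion, percentile-rescaled
    single-threshold positivity scoring, and immune-cell density
    quantification per region of interest. Includes a synthetic-data
    module that renders multispectral images with per-cell ground truth
    and simulates longitudinal weight-loss cohorts with programmed
    within-subject correlation structure, plus cohort statistics:
    Kruskal-Wallis tests with Dunn's post hoc (Sidak or
    Benjamini-Hochberg adjustment), distributional diagnostics, and
    subject-bootstrapped repeated-measures correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    mclust,
    MASS,
    car,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
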