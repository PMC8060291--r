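Package: darkchannel
Title: Dark-Channel Biomarker Discovery for Cell-Free RNA Liquid Biopsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovery of tumor-derived cell-free RNA (cfRNA) biomarkers from
    plasma whole-transcriptome strict-read counts. Implements reads-per-million
    normalization, dark-channel identification (genes with zero median and low
    standard deviation in non-cancer plasma), dark-channel biomarker (DCB)
    calling with a negative-binomial two-group test, tissue deconvolution by
    constrained least squares over tissue-specificity-score signature genes,
    tumor-content computation from matched cfDNA tumor fraction and tumor-tissue
    expression, and heterogeneous differential expression (heteroDE): a per-gene
    negative-binomial GLM on tumor content with bimodality (Poisson + Normal
    mixture EM) and influential-outlier (Cook's distance refit) false-positive
    filters. A synthetic-cohort generator with full ground truth makes every
    stage testable without access to restricted patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
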