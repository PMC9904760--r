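Package: hspcflow
Title: Reference-Based Annotation and Perturbation Analysis of HSPC scRNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational pipeline for annotating hematopoietic
    stem/progenitor cell (HSPC) single-cell RNA-seq data against a labeled
    reference and for detecting condition-associated perturbations. Provides
    a negative-binomial synthetic count simulator with ground truth, quality
    control and log-normalization, highly-variable-gene selection, a
    one-vs-rest elastic-net logistic regression classifier ensemble,
    cell-composition proportion testing with Holm correction, weighted
    pseudotime gene-trend fitting and comparison, and post-inference regulon
    analytics (batch centering, bimodal binarization, specificity scoring,
    network trimming).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    mgcv,
    mclust,
    limma,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
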