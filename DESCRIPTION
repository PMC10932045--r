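Package: cernascreen
Title: Immune-Related ceRNA Pair Screening for Case-Control Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested reimplementation of the screening cascade used to
    nominate immune-related lncRNA-mRNA competing endogenous RNA (ceRNA)
    pairs from bulk case-control RNA-seq count data: low-count filtering and
    median-of-ratios normalization, differential-expression screening,
    weighted gene co-expression module detection (soft threshold, topological
    overlap, module eigengenes, module-trait correlation), intersection with
    an immune gene list, three-criterion pair screening (positive expression
    correlation, shared regulatory miRNAs, differential expression of both
    members), independent-cohort replication, and signature-based immune-cell
    deconvolution with fraction-expression correlation.  A synthetic cohort
    generator with planted modules, pairs, decoys, and cell-type mixtures
    provides a recoverable ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
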