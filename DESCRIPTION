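Package: omicselect
Title: Elastic-Net Selection of Multi-Omic Predictors of Gene Signatures
Version: 0.1.0
Authors@R:
    person("omicselect", "developers", email = "omicselect@example.org",
           role = c("aut", "cre"))
Description: Fits per-gene elastic-net models over concatenated DNA
    methylation, transcript and miRNA predictor matrices, one model per
    phenotype, and analyses the selected predictors: omic-wise contribution
    by coefficient masking, enrichment for known regulator-target links,
    directed predictor-gene networks with hub and knockout analysis,
    fold-change-thresholded moderated differential expression, and gene-set
    enrichment of selected transcripts. Includes a synthetic multi-omic data
    generator with planted regulatory ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    limma
Config/testthat/edition: 3
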