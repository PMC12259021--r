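Package: stagehet
Title: Stage-Wise Transcriptional Heterogeneity and Gene-Program Scoring
    for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies within-stage transcriptional heterogeneity in
    multi-stage single-cell RNA-seq studies (e.g. premalignant progression
    series) using the median pairwise normalized mutual information between
    discretized cell profiles under a repeated-subsampling design, together
    with the surrounding pipeline: cell and gene quality control,
    library-size log normalization, one-vs-rest Wilcoxon marker ranking,
    feature-panel construction, expression-bin-matched gene-set module
    scores, gene-set and cell-group Pearson correlations, and a negative
    binomial multi-stage count simulator with known ground truth for
    validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
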