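Package: pathomine
Title: Literature Mining of Disease-Gene Associations from Biomedical
    Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for mining latent disease-gene associations from
    entity-tagged biomedical abstracts: corpus preprocessing with
    multi-word named-entity merging, skip-gram word embeddings trained
    from scratch with negative sampling, document classification for
    stratifying pathology-relevant abstracts, cosine association scores
    ("Patho-scores") with Monte-Carlo empirical p-values, ROC
    benchmarking against curated disease-gene pairs, genomic hotspot
    binning, and random walk with restart on a multiplex
    disease-gene-protein network for candidate prioritisation.  A
    synthetic-corpus generator with planted gene-disease co-occurrence
    structure supports end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    Matrix,
    methods,
    nnet,
    ranger,
    Rcpp,
    stats,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
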