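Package: tnbk
Title: Two-Phase k-mer Naive Bayes Classification of Tissue-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts tissue-specific gene expression classes from promoter DNA or
    protein sequence alone. Phase I trains, per tissue, a k-mer naive Bayes
    classifier NB(k) equivalent to an order-(k-1) Markov chain likelihood with
    additive smoothing; the per-tissue Phase I predictions form a cross-tissue
    feature vector classified in Phase II (tNB(k)) by a standard learner (naive
    Bayes network, decision tree, k-nearest neighbour, or linear support vector
    machine). Includes percentile-based expression labeling with balanced
    negative sampling, mean imputation of missing feature slots, stratified
    10-fold cross-validation with pooled confusion metrics, the full experiment
    grid, promoter extraction from genome plus GFF3 annotation, and a seeded
    synthetic generator (planted Markov chains, Gaussian-copula correlated
    tissue labels) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    jsonlite,
    e1071,
    rpart,
    class,
    withr,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
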