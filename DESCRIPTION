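Package: miRTails
Title: IsomiR and Nontemplated 3' Tail Profiling for Small RNA Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to profile microRNA 3' end variants (isomiRs) from small
    RNA sequencing libraries. Implements NEXTFlex-style read preprocessing
    (adapter trimming, 4-nt UMI removal and deduplication), assignment of
    reads to mature miRNA arms, greedy decomposition of 3' ends into
    templated extensions versus nontemplated tails, an isomiR taxonomy and
    tail typology (mono/di/oligo uridylation and adenylation), summary
    statistics for tail usage including weighted mean ratios, condition
    comparisons with fold-change quadrants, 5p/3p arm ratios and arm-switch
    detection, a negative-binomial Wald test for differential expression
    with Benjamini-Hochberg correction, k-means clustering of fold-change
    profiles, hypergeometric set enrichment, miRNA-mRNA anticorrelation
    edge filtering, and logistic growth-curve fitting. A synthetic-data
    generator produces reference hairpins, FASTQ reads and count tables
    with known ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, Transcriptomics, DifferentialExpression,
    Preprocessing, Clustering
RoxygenNote: 7.3.3
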