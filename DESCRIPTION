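Package: awmnet
Title: Association Weight Matrix Co-Association Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-trait systems-genetics pipeline around the association
    weight matrix (AWM): mixed linear model GWAS with a genomic relationship
    matrix and profile-REML heritability, key-phenotype and pleiotropy-aware
    SNP selection, gene-anchored matrices of standardized SNP effects, gene
    co-association network inference with the partial correlation and
    information theory (PCIT) algorithm, regulator-trio ranking and greedy
    key-regulator selection, plus a ground-truth synthetic data generator
    (genotypes with LD, correlated polygenic traits with fixed effects,
    gene annotation and a regulator census) so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
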