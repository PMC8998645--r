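Package: rlrkit
Title: Molecular Evolution Toolkit for RIG-I-Like Receptor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the molecular evolution of RIG-I-like
    receptor (RLR) gene families: parsing gene models from GFF3/FASTA,
    classifying protein domain architectures into an RLR type taxonomy,
    detecting tandem duplication arrays from scaffold gene orders,
    classifying the mechanisms of exon-intron structural divergence
    between sibling paralogs/orthologs (gain/loss of exon or intron,
    exonization/pseudoexonization, intraexonic insertion/deletion),
    FPKM-based expression profiling with a negative-binomial exact test
    for differential expression, and Goldman-Yang (GY94) codon-model
    likelihood machinery (M0, two-ratio branch model, M1a/M2a, M7/M8)
    with likelihood-ratio tests and empirical-Bayes identification of
    positively selected sites. Includes synthetic-data generators that
    emit every input format with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
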