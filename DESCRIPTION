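Package: seqexpr
Title: Cell-Population-Specific Gene Expression Prediction from Promoter Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-cell-population gene expression (pseudobulk of
    single-cell RNA-seq) from the genomic sequence around the transcription
    start site plus five mRNA half-life proxy features, using a multitask
    one-dimensional convolutional neural network trained with backpropagation
    and the Adam optimizer. Includes transcript selection and strand-aware
    promoter-window extraction from GTF/FASTA, IUPAC-aware one-hot encoding,
    pseudobulk aggregation with sentinel handling for unexpressed genes,
    cross-validation fold construction (random-gene and cross-chromosome),
    in-silico saturation mutagenesis for regulatory-variant prioritization,
    and a seeded synthetic-data generator with planted population-specific
    motifs for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
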