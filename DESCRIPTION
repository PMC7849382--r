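Package: cpgactivity
Title: Predicting Single-Cell Gene Activity from Sparse Promoter CpG
    Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised prediction of per-cell gene activity scores from
    sparse single-cell bisulfite-sequencing data. Cells are smoothed into
    meta-cells by k-nearest-neighbour pooling in a PCA embedding of
    promoter methylation; each gene/meta-cell pair is summarised by binned
    promoter CpG-dinucleotide frequencies and binned pooled methylation
    rates; and an ensemble of a 1-D convolutional network, an elastic net
    and a random forest regresses these features onto normalized
    expression measured by joint methylome+transcriptome protocols.
    Includes a mean promoter demethylation (MPD) baseline, permutation
    feature importance, internal and external cross-validation with
    CpG-context stratification, a synthetic multi-omics data generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    Matrix,
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
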