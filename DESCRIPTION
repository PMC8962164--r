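Package: hashdemux
Title: Demultiplexing Cell Hashing Data from Droplet Single-Cell Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for demultiplexing Cell Hashing single-cell RNA-seq
    experiments in which samples labelled with Hash Tag Oligos (HTOs) are
    pooled across 10x Genomics wells. Counts hashtag reads per cell barcode
    from paired FASTQ with quality-aware barcode correction and UMI
    deduplication, derives per-tag count cutoffs by a dip-test / 1-D 2-means
    procedure, classifies cell barcodes as singlet, doublet, multiplet or
    no-hash, and splits and merges Cell Ranger style HDF5 feature-barcode
    matrices into per-sample outputs with machine-readable metric reports.
    Includes a seeded synthetic-data generator producing ground-truthed HTO
    FASTQ, count matrices and expression wells for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    rhdf5,
    rlang,
    ShortRead,
    stats,
    tibble,
    utils,
    uuid,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
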