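Package: snhash
Title: Sample Demultiplexing and Peak Analysis for Hashed Single-Nucleus ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for antibody-hashing based sample multiplexing of
    single-nucleus ATAC-seq. Parses structured hashing reads (anchors, dual
    UMIs, sample barcode) from FASTQ, corrects cell barcodes against a
    whitelist, collapses UMIs with a directional adjacency rule, and builds a
    valid-cell by sample hash count matrix. Classifies nuclei as singlet,
    multiplet or negative by count cutoffs (fixed, mixture-model, or
    CLR-quantile), assigns species in barnyard (two-genome) designs, and
    quantifies concordance between hash-based and alignment-based calls.
    Categorizes single-cell peaks by the number of cell clusters in which they
    appear, attaches bulk ATAC intensities, dichotomizes bimodal intensity
    distributions, and annotates peaks by genomic feature. Includes a
    synthetic-data generator with full ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    GenomeInfoDb,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
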