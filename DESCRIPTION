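Package: ifnkit
Title: Interferon-Stimulated Gene Signatures and Promoter Motif Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for type I interferon (IFN)
    transcriptomics in mixed immune-cell populations. Assigns fixed-length
    promoters to transcripts by matching ENCODE-style promoter-like elements
    near transcription start sites (or imputing around them), scores promoters
    against position weight matrix libraries with reference-standardised
    motif-cluster Z-scores, and tests motif-cluster scores for association
    with IFN-induced fold changes by Mann-Whitney U. Provides differential
    expression set algebra (universal and subtype-specific gene sets, lineage
    Venn partitions), Seurat-style single-cell Wilcoxon differential
    expression, core interferon-stimulated gene (ISG) intersection, per-cell
    ISG scores, and co-regulation classification of divergent and antisense
    non-coding RNAs against their protein-coding neighbours. Includes a
    ground-truth synthetic data generator emulating a multi-donor,
    multi-IFN PBMC stimulation experiment so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
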