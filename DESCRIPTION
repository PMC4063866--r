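Package: bsmethy
Title: Whole-Genome Bisulfite Sequencing Alignment, Methylation Calling
    and Differentially Methylated Region Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis pipeline for whole-genome bisulfite
    sequencing (MethylC-seq style libraries). Aligns bisulfite reads by
    in-silico C-to-T conversion against both converted reference strands,
    computes per-cytosine methylation calls with trinucleotide context,
    estimates methylation densities for regions, windows and sequence
    contexts, identifies differentially methylated regions between two
    samples with a four-stage sliding-window algorithm (Mann-Whitney U
    seed test, extension, merging and a chi-square region test), reports
    alignment and methylation QC, compares sequencing-derived methylation
    with methylation-array beta values, and simulates bisulfite read
    pairs with full truth tracking for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    readr,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
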