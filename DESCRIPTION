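Package: conseqr
Title: Consensus Calling and Error Correction for Molecule-Tagged Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for processing amplicon sequencing reads that carry random
    molecule tags (unique molecular identifiers). Reads are decomposed into
    tag, primer and amplicon regions with IUPAC-aware pattern matching, binned
    by tag, stacked into per-tag alignment matrices, and collapsed into
    error-corrected consensus sequences using Phred-quality-weighted mode base
    calling with IUPAC fallback. Includes FLASH-style overlapping paired-end
    merging, confidence (c-score) filtering of low-quality and tag-collision
    consensus sequences, digital normalization, a molecule-tagged read
    simulator with ground truth for benchmarking, and errors-per-base
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
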