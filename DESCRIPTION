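Package: clipsplice
Title: Integrative iCLIP and Differential-Splicing Analysis of Splicing-Regulator Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for identifying the
    direct targets of an RNA-binding splicing regulator. From barcoded iCLIP
    alignments it removes PCR duplicates, calls single-nucleotide crosslink
    sites, assigns each site a permutation-based positional false discovery
    rate, merges significant sites into binding clusters, and scores pentamer
    motif enrichment against intron-matched random intervals. From
    cassette-exon junction counts it estimates percent-spliced-in (PSI),
    tests differential splicing between conditions, and classifies exons by
    their response to regulator depletion versus differentiation. Binding,
    splicing response, expression changes (Welch's t-test on FPKM), and
    ChIP-cluster gene assignment are combined into direct-target calls with
    hypergeometric overlap enrichment. A synthetic-data module generates
    genome, annotation, reads, junction counts, expression tables, and ChIP
    clusters with known ground truth, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
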