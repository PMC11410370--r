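Package: promocc
Title: Promoter Occupancy Analysis for ChIP-seq, CAGE-seq and RNA-seq Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of transcription-factor promoter occupancy.
    Implements base-pair Jaccard and relative-distance interval statistics,
    peak-to-gene classification, IUPAC and position-weight-matrix motif
    scanning with exact p-value thresholds, CAGE tag clustering (distance and
    paraclu maximal-density methods) with dominant-TSS calling, core-promoter
    element architecture around empirically mapped TSSs, coverage
    metaprofiles (reference-point and scale-regions), and Fisher integration
    of binding with differential expression. Ships a seeded synthetic-data
    generator that plants known peak overlap, motif content, CAGE signal and
    bound-by-expression odds ratios so every stage can be tested against
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
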