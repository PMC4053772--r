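Package: prc1targets
Title: Co-Occupancy Calling and Target-Gene Classification for PRC1 ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-factor, per-replicate ChIP-seq peak calls for Polycomb
    repressive complex 1 (PRC1) orthologs into co-occupancy sites bound by at
    least one CBX and one RING protein together with H3K27me3, assigns those
    sites to candidate target genes by nearest transcription start site with a
    coding-gene preference, classifies the peak architecture of each target
    (TSS-associated, TES-associated, both ends, or ambiguous), integrates
    duplicate RNA-seq read counts under a ten-read activity threshold, and
    compares target-gene sets between fibroblast strains and binding profiles
    between proliferating and senescent conditions. Ships a fully labelled
    synthetic peak-landscape generator so every stage can be validated against
    planted ground truth without the original deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
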