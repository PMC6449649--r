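Package: difmod
Title: Detection and Analysis of Xer/dif Recombination Sites and dif Modules in Bacterial Replicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 28-bp Xer recombinase (XerC/XerD) dif sites in plasmid and
    chromosomal sequences by fixed-length similarity scanning against a reference
    site pair, calls cargo-carrying dif modules between consecutive sites, assesses
    module mobility from sequence identity and flanking-context divergence, clusters
    sites at an identity threshold, builds per-position nucleotide frequency and
    information-content profiles for site groups, and summarises site burden across
    plasmid collections. Includes a synthetic-replicon generator with full planted
    ground truth for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
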