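Package: bimodalseed
Title: Internal-Seed miRNA Target Analysis with Word Enrichment, Duplex
    Energetics and Seed-Anchored CLIP Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and characterising non-canonical miRNA
    seed activity, in particular "internal seed" matching in which a
    mature miRNA engages targets through positions 6-12 rather than the
    canonical 2-8 seed. The package derives target words from arbitrary
    seed windows (including 5' isomiR-shifted variants), scans 3'UTR sets
    for matches, computes Sylamer-style hypergeometric word-enrichment
    landscapes over ranked differential-expression lists, compares log
    fold-change distributions across seed classes with ECDF/KS analysis,
    screens candidate sites with a nearest-neighbour RNA duplex
    minimum-free-energy model, calls seed-anchored AGO-CLIP peaks against
    matched controls, profiles 5' isomiR offsets from small-RNA
    alignments, and normalises qPCR panels (CNRQ) for correlation
    analysis. A fully deterministic synthetic-data generator with a
    ground-truth manifest supports end-to-end benchmarking of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
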