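Package: meristemethyl
Title: Windowed DMR Calling and TE-Edge Methylation Profiling for Plant Meristem Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome bisulfite sequencing of plant
    shoot apical meristems: aggregates per-cytosine methylation calls into
    fixed-width genomic windows per sequence context (CG, CHG, CHH), calls
    differentially methylated regions between two samples with Fisher's exact
    test, Benjamini-Hochberg FDR control, context-specific difference
    thresholds and distance-based merging, attributes DMRs to genes and
    transposable-element families by overlapping base pairs, computes
    edge-anchored metagene profiles of methylation and 24-nt small-RNA
    abundance, summarises small-RNA size classes and normalised emPAI protein
    abundances, and tests germ-cell/meristem hypermethylation set overlap.
    Includes a deterministic synthetic-data generator (toy genome,
    annotations, beta-binomial cytosine reports, small-RNA reads, and ground
    truth) so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
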