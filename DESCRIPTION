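Package: cypfam
Title: Genome-Wide Cytochrome P450 Family Expansion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for genome-wide comparative analysis of cytochrome P450
    (CYP) complements in fungal genomes. Authenticates candidate P450
    proteins by their two signature motifs (the FXXGXXXCXG heme-binding
    decapeptide and the K-helix EXXR motif), builds species-by-family
    census tables with a fractional enrichment cutoff, infers minimum
    evolution phylogenies from Poisson-corrected protein distances
    (neighbor-joining start, ordinary least-squares branch lengths,
    close-neighbor-interchange search), compares exon-intron gene
    structures to call paralog clusters and cross-species ortholog
    candidates, detects tandem gene arrays on scaffolds, and summarises
    intron counts per family. A seeded synthetic genome-annotation
    generator with planted truth labels supports end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    rtracklayer,
    jsonlite,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
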