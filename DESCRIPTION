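Package: nbsatlas
Title: Genome-Wide Identification and Genomic Context Analysis of NBS-LRR
    Disease Resistance Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-scale surveys of nucleotide-binding-site (NBS)
    disease resistance genes in plant genomes. Calls the five strictly
    ordered NBS motifs (P-loop, kinase-2, kinase-3a, GLPL, MHDL) with a
    degenerate-pattern scanner, grades N-terminal coiled-coil signal with a
    windowed heptad-register score at MARCOIL-style probability thresholds,
    ingests InterProScan-style domain evidence and BLAST tabular homology
    hits, and assigns each gene a regularity class and a composed letter
    code (e.g. CNL, cNX, TNL). Detects 200-kb gene clusters, 70/70
    coverage-identity duplication events and single-linkage gene families,
    builds neighbor-joining trees with bootstrap support and clade-monophyly
    tests, places QTL markers by electronic PCR and classifies their
    co-localization with NBS genes, and ships a seeded synthetic-genome
    generator with planted ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
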