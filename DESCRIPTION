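Package: g4census
Title: Genome-Wide G-Quadruplex Census for Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: G4Hunter-based detection of putative quadruplex-forming
    sequences (PQS) in bacterial genomes, with a score-interval census,
    feature-neighborhood localization (before/inside/after annotated
    features), and cohort-level frequency statistics across phylogenetic
    groups (Kruskal-Wallis comparison, GC-normalized outlier flagging).
    Reads genome FASTA files and NCBI tab-delimited feature tables, and
    includes a synthetic-genome generator with planted G-rich tracts so
    every pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
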