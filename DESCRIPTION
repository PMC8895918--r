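Package: ighrep
Title: Similarity Analysis of Immunoglobulin Heavy-Chain Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how similar B cell receptor (BCR) heavy-chain
    repertoires are between individuals, tissues and antibody isotypes.
    Provides isotype demultiplexing of raw reads by constant-region primer
    matching, qualified-clone filtering of AIRR rearrangement tables,
    V/D/J gene-usage profiles with Pearson correlation, CDR3 clonotype
    profiles with the Morisita-Horn similarity index and normalized Shannon
    diversity entropy, Chao1 richness with rarefaction/extrapolation and
    sequencing coverage, clonal-lineage network inference by CDR3 nucleotide
    identity within V/J/length groups, cross-individual lineage sharing and
    occupancy analysis, and a seeded synthetic-repertoire generator with
    planted lineage, sharing and abundance structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
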