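Package: paleomito
Title: Reference-Guided Assembly and Analysis of Ancient Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing mitochondrial genomes from ancient DNA
    shotgun reads: a synthetic ancient-read simulator with terminal
    deamination damage, adapter trimming, bounded-edit-distance ungapped
    mapping to circular genomes, competitive multi-reference species
    assignment with in-silico PCR, iterative damage-aware reference-guided
    consensus assembly with PCR evidence integration, terminal
    misincorporation profiling, pairwise genome comparison with
    transition/transversion and codon-position classification, annotation
    lift-over with coding-sequence validation under the vertebrate
    mitochondrial genetic code, and neighbor-joining phylogenetic placement
    with bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
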