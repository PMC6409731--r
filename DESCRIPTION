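Package: famevol
Title: Gene Family Evolution: Phylogeny, Reconciliation, Duplication Dating,
    Site Selection and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for studying the evolution of a plant gene family
    such as the vacuolar iron transporters (VITs): neighbor-joining
    phylogenies from p-distances with bootstrap support, gene-tree/
    species-tree reconciliation under duplication-loss parsimony with
    ancestral copy-number inference, classification of paralog pairs into
    tandem, segmental and transposition duplications from genome
    coordinates and synteny blocks, Nei-Gojobori Ka/Ks estimation and
    molecular-clock dating (T = Ks / 2 lambda), site-specific selection
    inference under discretized omega-distribution codon models (M5, M7,
    M8) with empirical-Bayes posterior omega per site, intron phase and
    intron-retention analysis, and expression summaries from FPKM and
    qPCR CT tables via the 2^-ddCT method. A synthetic-data module
    generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
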