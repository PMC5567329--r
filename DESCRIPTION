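Package: panstrep
Title: Bacterial Pan-Genome Construction, Rarefaction Curves and Average
    Nucleotide Identity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of bacterial strain sets in the
    style of Streptomyces pan-genome studies: iterative gene-pool accretion
    with BLAST-coverage-ratio (BCR) homology calling, core/dispensable/
    strain-specific partitioning, pan- and core-genome rarefaction curves
    with exponential-decay and power-law fits, fragment-based average
    nucleotide identity (ANIb-style), gene-family presence/absence
    phylogenies, and per-genome feature statistics. Includes a synthetic
    pan-genome simulator with ground-truth family labels so every stage can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
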