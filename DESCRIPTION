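Package: spidroinr
Title: Design and Assembly Analysis of Recombinant Spidroin Mimics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing beta-sheet-rich recombinant spider silk
    proteins (spidroins) and quantifying their self-assembly. Mines beta-strand
    motifs from secondary-structure-annotated sequences and screens them by
    frequency, composition and Chou-Fasman strand propensity; builds chimeric
    MaSp1-derived constructs by poly-alanine shortening or motif substitution,
    simulates NheI/SpeI compatible-cohesive-end repeat doubling and performs
    deterministic codon optimization with restriction-site avoidance; and
    computes radius of gyration, RMSF, RMSD, Shrake-Rupley solvent-accessible
    surface area and inter-chain centre-of-mass distance from coarse-grained
    bead trajectories, with an explicit assembly verdict. Includes seeded
    synthetic-data generators for strand corpora, template sequences and
    two-chain trajectories so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    bio3d,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
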