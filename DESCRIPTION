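Package: calmscape
Title: Conservation Mapping, Superposition and Split-Motif Analysis for
    Phycobilisome Scaffolding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising cryptophyte-alpha-like (CALM) domains in
    red algal phycobilisome scaffolding proteins: per-site Shannon entropy
    conservation profiles from protein multiple sequence alignments, painted
    onto structure B-factors for surface visualisation; rigid-body Kabsch
    superposition with iterative outlier rejection and structure-based
    sequence alignment; Shrake-Rupley solvent-accessible surface area, buried
    interface area and hydrophobic surface patch detection; and
    position-specific scoring matrix scanning for repeated three-segment
    split motifs. Includes seeded synthetic-data generators (alignments,
    structure pairs, two-chain complexes, motif-bearing sequence sets) with
    recorded ground truth so every analysis stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
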