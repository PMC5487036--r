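Package: cnasplit
Title: Design and In Silico Screening of Covalent Tag/Catcher Systems
    from CnaB-Type Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for deriving covalent split-protein (tag/catcher)
    systems from bacterial CnaB-type domains. Detects the reactive
    Lys-Asn/Asp-Glu/Asp isopeptide triad in a crystal structure, validates
    residue-range split specifications, builds capped tag and catcher
    constructs, sequence variants, point mutants and fusion proteins, and
    scores intact-domain versus split-system stability from molecular
    dynamics trajectories using core-region backbone RMSD, tag-catcher
    van der Waals interaction energy, beta-sheet hydrogen-bond distance
    persistence, secondary-structure content and a contact-based
    dissociation monitor. Includes seedable synthetic structure and
    trajectory generators so every metric is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    igraph,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
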