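Package: v4evo
Title: Secondary-Structure Evolution of the SSU rRNA V4 Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of the secondary structure of
    the V4 hypervariable region of the small-subunit (SSU) rRNA gene, with
    the ciliate genus Euplotes as the motivating system. The pipeline
    extracts the V4 region from full-length SSU sequences using conserved
    flanking anchors, predicts secondary structures by base-pair
    maximisation dynamic programming (per sequence and as an alignment
    consensus with a covariance bonus), applies structure curation rules,
    decomposes structures into helices and classifies the E23_8 helix
    topology as Type I (terminal hairpin) or Type II (two distal
    sub-helices, E23_11/E23_12), counts compensatory and
    hemi-compensatory base changes (CBC/hCBC) between taxa over shared
    paired columns, and reconstructs ancestral Type I/II states on a given
    phylogeny by parsimony, reporting gains and reversals. A seeded
    simulator generates trees, sequences, alignments and event logs with
    planted structural events so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
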