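Package: abloopr
Title: Sequence and Conformational Profiling of Antibody CDR-3 Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising antibody binding promiscuity from the
    third complementarity-determining regions (CDR-H3/CDR-L3) of paired
    heavy/light variable-domain sequences and from conformational ensembles of
    their loops. Provides anchor-motif CDR-3 extraction with Chothia-style
    numbering, Kidera-factor encoding and hierarchical clustering under a
    Minkowski metric with phenotype-enrichment reporting, beta-sheet propensity
    profiling of loop stems and apices, Kabsch-Sander hydrogen-bond based
    secondary-structure assignment over multi-model PDB ensembles with
    bootstrap occupancy statistics and group contrasts, and principal component
    analysis of loop trajectories to rank maximally dynamic residues.
    Includes seeded generators for labelled antibody-like sequence panels and
    constraint-respecting backbone ensembles with known ground truth.
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
    withr,
    readr,
    stringr,
    generics,
    ggplot2,
    ape,
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
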