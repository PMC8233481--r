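Package: ribolandscape
Title: Fitness-Landscape and Ancestral-Activity Analysis for Self-Cleaving Ribozyme Mutational Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of self-cleaving ribozyme
    activity with combinatorial mutational libraries and sequencing-based
    cleavage assays, modeled on the mammalian CPEB3 (HDV-like) ribozyme.
    Enumerates doped-library genotype spaces, simulates co-transcriptional
    self-cleavage assay reads with 5'-RACE phasing pads, classifies reads
    into cleaved and uncleaved states and estimates per-genotype fraction
    cleaved, reconstructs ancestral sequences on a species tree by Fitch
    parsimony and marginal maximum likelihood (JC69 or Tamura-Nei), assigns
    activities to tree nodes by measured values and structure-based rules,
    builds genotype networks above an activity threshold, enumerates viable
    mutational pathways and mutational neighborhoods, and classifies
    pairwise epistasis into magnitude, sign and reciprocal sign classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    Matrix,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
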