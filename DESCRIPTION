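Package: cypevol
Title: Birth-Death, Constraint and Dating Analysis of Cytochrome P450 Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of the cytochrome P450 (CYP)
    gene superfamily in vertebrates: distance-based phylogenies (p-distance,
    JTT, Nei-Gojobori dN/dS) with bootstrap support, reference-anchored
    classification of genes into biosynthesis (B) and detoxification (D)
    types, Dollo-parsimony reconstruction of gene gains, losses and
    pseudogenizations on a dated species tree with per-100-myr rate
    estimation, molecular-clock dating of duplications and pseudogenization
    events, least-squares estimation of functional constraint, and seeded
    simulators of gene content and codon sequence evolution for validating
    every stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
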