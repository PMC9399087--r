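Package: cysbond
Title: Covalent TCR-pMHC Recognition: CDR3 Cysteine-Index Repertoire
    Statistics and Two-Phase Binding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying disulfide-capable T cell receptors.
    Implements the CDR3 cysteine index (the percentage of clones in an immune
    repertoire sample carrying a cysteine within two positions of the CDR3
    apex, with detection-count and Trbv1 germline-cysteine exclusion rules),
    reference-catalog clonotype distribution statistics for AIRR-format clone
    tables, a two-phase (noncovalent then covalent) receptor-ligand binding
    kinetics model with surface plasmon resonance sensorgram simulation,
    steady-state 1:1 Langmuir fitting, occupancy normalization and
    dissociation decomposition, tetramer-decay modelling, and four-parameter
    logistic dose-response fitting with bootstrap confidence intervals.
    Includes seeded synthetic-data generators so every analysis is
    exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
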