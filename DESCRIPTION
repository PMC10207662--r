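Package: driverpath
Title: Driver Pathway Identification from Somatic Mutations by Coverage,
    Mutual Exclusivity and Network Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate cancer driver pathways from a binary
    somatic mutation matrix and a weighted gene-association network. A
    parameter-free objective combines sample coverage, a mutual-exclusivity
    measure built on relative Hamming distances between gene mutation
    profiles, and average pairwise network connectivity; gene sets of a
    chosen size are found with a clustering-seeded partheno-genetic
    algorithm (single-parent greedy recombination with roulette selection
    and elitism). Includes the classical maximum-weight-submatrix score as
    a baseline, detection of inclusion relationships between mutation
    profiles, a random-set permutation significance test, a planted-module
    synthetic data generator, readers for TSV mutation matrices and
    STRING-style association edge lists, broom-style tidiers and ggplot2
    plotting methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
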