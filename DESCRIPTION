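Package: layersim
Title: Rules-Based Simulation of Epigenomic State Layers on Genome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the genome-wide accumulation of epigenetic state by
    repeated, stochastic action of 'binding factors' on a genome sequence.
    A layer set couples an immutable genome with any number of named binary
    interval layers; binding factors match combinations of sequence patterns
    (IUPAC consensus, position weight matrix, or regular expression) and
    layer states, then set layers present or absent over a configurable
    state width around each match.  Includes abundance-limited cycle
    simulation with seeded replicates, per-base replicate coverage
    aggregation, a synthetic-genome generator with planted ground truth,
    ready-built models of yeast SIR telomeric silencing and of human
    pluripotency-factor activation against a CpG-island repressor, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
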