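Package: tripletr
Title: Fidelity and Substrate-Pool Analysis for Triplet-Based RNA Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for RNA-catalysed RNA synthesis from trinucleotide
    triphosphate (triplet) substrates. Implements deep-sequencing fidelity
    profiling of triplet polymerase ribozymes (primer-variant demultiplexing,
    triplet counting, positive-control background correction, positional error
    collation and geometric-mean fidelity summaries), reference-based segment
    fidelity with mutation filtering, ligation-extent statistics from
    extension-product ladders, cooperative (Hill) dose-response fitting for
    substrate invasion of structured templates, and a mass-action
    triplet:anti-triplet dimerization equilibrium model for substrate pools.
    Ships seeded simulators for every input so the full pipeline is testable
    with known ground truth.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
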