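Package: conformscape
Title: Conformational Landscapes, Markov State Models and Coupled-Evolution
    Analysis for Receptor Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the conformational space of G
    protein-coupled receptors from molecular dynamics output: collective
    variables built on Ballesteros-Weinstein numbering (transmembrane
    distance sums and the helix-8 dihedral), per-residue fluctuation,
    principal-component and dynamic cross-correlation analysis,
    Boltzmann-inverted free-energy landscapes, Markov state models with
    implied-timescale testing, PCCA+ macrostate lumping and
    transition-path statistics, statistical coupling analysis of multiple
    sequence alignments with eigenvector-defined sectors, and a nudged
    elastic band minimum-energy-path finder on analytic potential
    surfaces. Synthetic generators (Brownian dynamics on multi-well
    surfaces, Markov-chain label sequences, sector-planted alignments and
    idealised helix bundles) provide ground truth so every stage is
    testable without large trajectory archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
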