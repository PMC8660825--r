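Package: g2mcycle
Title: Coupled Mitotic Cell Cycle and G2/M DNA Damage Checkpoint Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ODE model of the mammalian mitotic cell cycle
    coupled to the G2/M DNA damage checkpoint (p53-Mdm2-Wip1 oscillator,
    ATM/ATR signalling, and the Mad2:Cdc20 mitotic checkpoint complex).
    Provides a stiff integrator with checkpoint event handling, limit-cycle
    period estimation and phenotype classification, an in-silico perturbation
    engine (gene deletions, Plk1 depletion, CRISPR-style knockouts, cancer
    cell-line mutation profiles), and three parameter sensitivity analyses
    (logarithmic intensities, partial rank correlation over Latin-hypercube
    samples, and fuzzy alpha-cut uncertainty bands).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
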