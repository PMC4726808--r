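Package: qlbn
Title: Quantum-Like Bayesian Networks for Decision Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Exact inference over small Bayesian networks of binary variables
    in which classical probabilities are replaced by Born-rule probability
    amplitudes, producing interference terms between unobserved completions.
    The interference phase is set automatically by a similarity heuristic
    built from law-of-cosines angles between outcome vectors, which lets the
    network predict (rather than merely explain) violations of the Sure Thing
    Principle observed in Prisoner's Dilemma and two-stage gambling
    experiments. Includes the classical law-of-total-probability and Quantum
    Prospect Decision Theory quarter-law baselines, embedded literature
    fixtures, phase sweeps, and a reproduction harness for published
    comparison tables.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
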