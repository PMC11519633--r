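Package: plantdefense
Title: Plant-Herbivore Compartment Models of Constitutive Chemical Defense
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic compartment models of plant populations attacked by
    generalist insect herbivores, with and without constitutive chemical
    defense. Implements the susceptible-exploited-insect (SEI) and
    susceptible-exploited-defended-insect (SEDI) ordinary differential
    equation systems, the insect reproduction number R0 = eta*beta/gamma,
    closed-form free and endemic equilibria with existence conditions,
    Jacobian eigenvalue stability classification, adaptive time integration
    with equilibrium detection and conservation auditing, the herd-defense
    threshold p > 1 - 1/R0 for the defended fraction of germinating plants,
    a registry of figure scenarios, and (p, R0) phase-diagram sweeps
    comparing analytic and simulated outcomes. Results are returned as
    tibbles with tidy()/glance() methods and ggplot2 autoplot() figures;
    a thin command-line interface is included.
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
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
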