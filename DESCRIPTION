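Package: snnmanifold
Title: Operational Manifolds, Efficiency Scores and Drift Diagnostics for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the operational manifold of leaky
    integrate-and-fire (LIF) spiking neural networks: a discrete-time LIF
    simulator with hard/soft reset and refractory handling, surrogate-gradient
    training of small multilayer and convolutional spiking networks, grid
    sweeps over the membrane time constant and firing threshold that locate
    silent, balanced and saturated regimes, synaptic-operation (SOP) energy
    proxies with composite accuracy-energy scores, reset-versus-carry
    inference-state policies, and correlation-based diagnostics of noise
    exposure and concept drift. Ships seeded synthetic task generators so
    every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    withr,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
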