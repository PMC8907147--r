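Package: reedsim
Title: Replica-Exchange Enveloping Distribution Sampling on Analytic Toy Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multistate free-energy estimation with enveloping distribution
    sampling (EDS) and Hamiltonian replica exchange over the smoothing
    parameter (RE-EDS), together with the automated parameter pipeline:
    lower-bound detection for the replica ladder, per-state coordinate
    optimization, parallel energy-offset estimation (PEOE), round-trip-time
    ladder optimization (N-LRTO), energy-offset rebalancing, and multistate
    Zwanzig free-energy estimation with Gaussian and bootstrap uncertainties.
    End states are analytic toy potentials (harmonic oscillators and
    one-dimensional multi-well polynomials) with closed-form or quadrature
    free-energy oracles, so every pipeline stage is testable without
    molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
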