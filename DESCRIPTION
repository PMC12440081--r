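Package: ecoevogames
Title: Eco-Evolutionary Game Dynamics with Decoupled Intrinsic Selection
    and Ecological Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-type eco-evolutionary game dynamics in which the
    2x2 growth payoff matrix is decomposed into a cell-intrinsic selection
    coefficient and two ecological interaction coefficients. Provides the
    frequency-dependent selection coefficient and replicator dynamics,
    analytic conditions under which interactions maintain, mask, mirror, or
    mimic intrinsic selection (in deterministic dynamics, at steady state,
    and at the mode of the mutation-selection stationary distribution), a
    frequency-dependent Wright-Fisher simulator with mutation and drift,
    payoff inference from mono- and co-culture growth-rate assays, and
    perpendicular distances from measured systems to the analytic regime
    surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
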