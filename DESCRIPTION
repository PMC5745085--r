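Package: vg1nodal
Title: Kinetic Models of Vg1-Nodal Heterodimer and Nodal Homodimer Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic models of TGF-beta ligand dimerization in the
    early zebrafish embryo, comparing heterodimer formation from a maternally
    preloaded Vg1 monomer pool (the "primed" scheme) against Nodal homodimer
    formation from a cold start. Provides deterministic ODE integration with
    piecewise windowed synthesis and conservation ledgers, closed-form oracles
    for degenerate limits, an exact stochastic simulation (Gillespie) twin of
    both reaction networks, onset-delay and time-to-threshold metrics, a
    synthetic-data generator with lognormal observation noise, and parameter
    recovery by log-scale least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
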