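Package: episwitch
Title: Deterministic and Stochastic Simulation of the Inflammatory Epigenetic
    Switch Driving Cell Transformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic model of the positive inflammatory feedback loop between
    NF-kB, Lin28, Let-7 microRNA, IL6, Ras, STAT3, miR-21 and PTEN that behaves
    as an irreversible bistable switch between a non-transformed and a
    transformed cell state. Provides the 14-variable ODE system with optional
    ceRNA and PTEN1-mRNA sponging extensions, stiff deterministic integration
    with time-windowed parameter perturbations and a scenario library,
    steady-state/bifurcation analysis with fold-point detection, an exact
    Gillespie stochastic counterpart with system-size scaling, heterogeneous
    cell-population simulation with endpoint classification and correlation
    statistics, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
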