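Package: CRNlogic
Title: Chemical Reaction Network Designs for Asynchronous Logic Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Builds and simulates chemical reaction network (CRN)
    implementations of asynchronous logic: an Approximate-Majority-based
    Muller C-element, latches, an arbiter, forks and joins, the six dual-rail
    Boolean gates, a Muller C-pipeline, a queue and a ripple-carry adder.
    Circuits use only uni- and bi-molecular catalytic reactions with uniform
    rates and a dual-rail signal encoding. Three simulation semantics are
    provided: deterministic mass-action ODEs, exact stochastic simulation of
    the induced continuous-time Markov chain (Gillespie direct method), and
    the linear noise approximation (mean plus covariance). Validation tools
    include dual-rail threshold logic, truth-table sweeps over all input
    assignments, debounced first-passage measurement, Monte-Carlo estimation
    of time-bounded temporal properties, and export of the CTMC to the PRISM
    model-checker format.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'parse.R'
    'network.R'
    'circuit.R'
    'trajectory.R'
    'simulate-ode.R'
    'simulate-ssa.R'
    'simulate-lna.R'
    'components.R'
    'gates.R'
    'circuits.R'
    'validation.R'
    'properties.R'
    'prism.R'
    'scenarios.R'
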