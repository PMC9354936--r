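Package: popgrid
Title: Grid-Based Population Density Simulation of N-Dimensional Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the activity of populations of spiking neurons with a
    numerical population density technique that works for neuron models of any
    dimension. The state space of a user-supplied ordinary differential
    equation model is discretized into a regular N-dimensional grid and a
    sparse transition matrix encoding the deterministic flow of probability
    mass is precomputed by recursive simplex subdivision. Poisson shot-noise
    input is handled each time step by solving the associated master equation
    with precalculated jump transitions. Networks of populations coupled by
    delayed average firing rates can be simulated from an XML configuration,
    and built-in Monte Carlo and finite-size direct simulators provide
    independent validation. Conductance-based leaky integrate-and-fire and
    Hodgkin-Huxley models are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
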