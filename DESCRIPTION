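Package: synprune
Title: Co-Evolving Attractor Networks with Activity-Dependent Synaptic Pruning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of an Amari-Hopfield attractor neural
    network whose synaptic graph evolves in time: edges are created and
    destroyed with global probabilities that drive the mean degree through a
    developmental pruning curve, and local probabilities that depend on each
    neuron's incoming current, closing a feedback loop between memory and
    topology. Includes the decoupled topological limit and its
    degree-distribution master equation, closed-form synaptic-density curves
    with nonlinear fitting, structural observables (homogeneity,
    assortativity, clustering and neighbour-degree spectra, discrete
    power-law tail fits), and drivers for phase-diagram, bistability and
    memory-capacity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
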