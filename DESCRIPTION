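Package: balancenet
Title: Balanced Excitation-Inhibition Spiking Networks with Structured Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how non-random synaptic connectivity shapes
    balanced excitation and inhibition in cortical network models. Provides
    generators for directed excitatory/inhibitory network topologies with
    exactly constant class-pair in-degrees (random, forwards-backwards ring
    lattice, rewired lattice with structurally-defined neuron classes, and
    embedded modular networks), a fast conductance-synapse leaky
    integrate-and-fire simulator with transmission delays and Poisson
    external drive, a model local field potential and two-level up/down-state
    (bistability) analysis, per-node signed motif-participation metrics that
    recover structural neuron classes from connectivity alone, and seeded
    experiment orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
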