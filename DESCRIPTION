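Package: vqemol
Title: Hybrid Quantum-Classical Electronic Structure for Drug Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Emulates a hybrid quantum-classical pipeline for computational
    drug design. A compact Gaussian-integral and restricted Hartree-Fock
    engine produces molecular integrals, which are folded into frozen-core
    active-space Hamiltonians, mapped to qubit operators by the parity
    transformation with two-qubit reduction, and solved with a single-layer
    hardware-efficient Ry-ansatz variational quantum eigensolver (VQE) with
    exact or shot-based measurement, a readout-error model and mitigation.
    Measured reduced density matrices couple the quantum solver to a
    conductor-like continuum solvation model, to analytic nuclear gradients
    for QM/MM Langevin dynamics with hot-swappable classical/quantum engines,
    to quantum-resource estimates for paired unitary coupled cluster, and to
    Gibbs free-energy reaction profiles with uncertainty propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
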