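Package: pingctc
Title: Phase-Locking and Communication-Through-Coherence Analysis of PING
    Gamma Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse entrainment and effective communication in an
    excitatory-inhibitory network generating gamma oscillations through the
    PING mechanism. Implements the exact (next-generation) mean-field model of
    a quadratic integrate-and-fire network with Lorentzian heterogeneity,
    limit-cycle and equilibrium characterization, the adjoint-equation
    infinitesimal phase response curve, phase-reduced stroboscopic maps with
    rotation numbers and Arnold tongues (numerical continuation and pulsatile
    closed forms), communication-through-coherence response factors on
    entrained orbits, two-input competition with vector-strength diagnostics,
    pulse-induced switching between attended streams, and a microscopic QIF
    network simulator used as spiking ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
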