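Package: tactosense
Title: Neuromorphic Tactile Encoding and Sensorimotor Transduction Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the afferent-to-efferent tactile pipeline of a
    biomimetic hand: Izhikevich spiking models of slowly and fast adapting
    type I mechanoreceptors driven by a 6x6 tactile sensor array, a second
    order cuneate layer integrating postsynaptic potentials under a
    divergence/convergence mapping with winner-take-all selection, spike
    train features (firing rate, first-spike latency, Victor-Purpura
    distance) with signal-detection-theory object discrimination, muscle
    synergy extraction from EMG by non-negative matrix factorization with a
    variance-accounted-for selection rule, identification of Laplace-domain
    sensorimotor transduction functions, and a minimal closed-loop grasp
    simulation. A seeded synthetic generator stands in for the physical
    sensor array, EMG recordings and robot logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
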