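Package: meadyn
Title: Network Dynamics Analysis for Multi-Electrode Array Recordings of
    Connected Cerebral Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multichannel extracellular recordings of
    axon-bundle-connected cerebral organoid pairs on multi-electrode arrays:
    band-pass filtering and threshold spike detection, burst detection and
    inter-compartment synchronized-burst pairing, wavelet band decomposition
    and coherence of local field potentials, phase-amplitude coupling
    (Kullback-Leibler normalized modulation index), neuronal-avalanche
    extraction with power-law fitting and a critical branching-process
    simulator, optogenetic entrainment and short-term plasticity metrics,
    and a Hodgkin-Huxley regular-spiking/fast-spiking two-population network
    model with virtual-MEA output. Includes ground-truthed synthetic-data
    generators for every analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
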