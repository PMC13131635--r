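Package: thetagamma
Title: Simulation and Analysis of Theta-Nested Gamma Oscillations in Entorhinal Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of a heterogeneous excitatory-inhibitory
    network of medial entorhinal cortex stellate cells and parvalbumin-positive
    fast-spiking interneurons under optogenetic-like theta-frequency conductance
    drive, producing pyramidal-interneuron network gamma (PING), together with the
    accompanying electrophysiology and voltage-imaging analysis pipeline: zero-phase
    Butterworth band filtering, analytic Morlet wavelet scalograms with theta-cycle
    averaging and quality control, current-LFP cross-correlation lag analysis,
    Hilbert-phase spike-locking statistics (vector strength and pairwise phase
    consistency), fluorescence spike extraction for negative-going voltage
    indicators, and correlation-based hierarchical clustering of neural ensembles
    with the inconsistency criterion and optimal leaf ordering. Includes synthetic
    data generators with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
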