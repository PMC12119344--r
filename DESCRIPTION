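Package: brainmf
Title: Multiscale Brain Simulation with Biophysical Mean-Field Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiscale simulation of cortical dynamics from single adaptive
    exponential integrate-and-fire (AdEx) neurons up to connectome-coupled
    whole-brain networks. Provides conductance-based AdEx spiking networks
    with a self-sustain/survival protocol, a semi-analytic transfer function
    (Erfc template with a fitted second-order effective threshold) estimated
    from single-neuron simulations, first- and second-order mean-field models
    with spike-frequency adaptation, fixed-point and critical-adaptation
    analysis of the slow-wave (UP/DOWN) bifurcation, whole-brain networks of
    mean-field nodes with conduction delays, and the emergent-state
    observables used to characterise anesthesia and NREM sleep: simulated
    BOLD and structure-function (SC-FC) correlation, and the perturbational
    complexity index (Lempel-Ziv) of evoked responses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    deSolve,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
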