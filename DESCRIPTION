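Package: phasebayes
Title: Bayesian Estimation of Coupled Phase-Oscillator Dynamics from Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts coupled phase-oscillator dynamics -- natural frequencies,
    pairwise Fourier interaction functions, and phase-noise intensities -- from
    multi-neuronal spike times alone. Spike times are interpolated to phase
    time series, and a conjugate normal-inverse-gamma Bayesian linear model
    estimates all parameters in closed form, with the harmonic count of each
    interaction function selected by model evidence. Downstream tools infer
    directed synaptic connectivity from the summed Fourier power of the
    estimated interactions (Otsu threshold, Matthews correlation coefficient),
    measure spike-train synchrony by a binned coherence index, derive
    theoretical interaction functions from phase response curves and synaptic
    input kernels (including an adjoint solver for user-supplied limit-cycle
    ODEs), and simulate ground-truth stochastic phase-oscillator networks so
    the full estimator can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    deSolve,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
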