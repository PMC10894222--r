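Package: vibratime
Title: Neural Coding Models of Tactile Duration and Intensity Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for the study of how rat barrel
    cortex (vS1) activity gives rise to the perception of vibration duration
    and intensity. Implements noisy vibration stimulus generation and the
    two-interval stimulus design; a linear-nonlinear-Poisson (LNP) model of
    single-neuron responses under vibrissal and optogenetic drive, with
    penalized maximum-likelihood fitting to binned PSTHs; a variational
    Bayesian Gaussian-mixture population model used to sample large surrogate
    cortical populations; a stochastic leaky-integrator model that transforms
    summed population spiking into a percept of elapsed time and predicts
    trial-by-trial choices; psychometric-function fitting with lapse
    parameters, irrelevant-feature bias measures, bootstrap and permutation
    statistics; and spike-train analyses (boundary-aware PSTH smoothing,
    onset/offset detection, rate-code versus count-code comparisons).
    Ground-truth synthetic-data generators make every stage testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
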