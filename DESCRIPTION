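Package: oscsync
Title: Point-Process Regression Linking Network Oscillations to Spike Synchrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits point-process generalized linear models for single-neuron
    spike trains in which the conditional intensity factors into a stimulus
    (PSTH) effect, a post-spike auto-history effect, and a circular-spline
    modulation by the phase of a network-wide oscillation.  Fitted intensities
    are used to predict pairwise spike synchrony under conditional
    independence, to form the synchrony ratio zeta (observed over predicted
    near-coincident spikes), and to test log zeta = 0 by parametric bootstrap.
    Includes simulators for oscillation-driven GLM neurons and
    synchrony-injected pairs, the transition-operator theory of spike-phase
    histogram bias for non-Poisson firing, power analysis for synchrony
    detection, and LFP preprocessing (band-pass filtering, instantaneous
    phase, neighbor averaging, spike-triggered averages).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    splines,
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
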