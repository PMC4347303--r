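Package: hierCP
Title: Hierarchical Spiking-Network Simulation and Choice Probability Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-stage spiking network model of perceptual decision
    making -- a balanced sensory circuit of leaky integrate-and-fire neurons
    reciprocally coupled to a winner-take-all attractor circuit -- and provides
    the accompanying analysis suite: spike-count statistics (Fano factors,
    noise correlations with shift correction, adjusted count windows),
    choice-probability (ROC) time courses and their across-neuron stability,
    psychophysical reverse correlation with integration-window extraction,
    Weibull psychometric fits, and the stability-accuracy trade-off between
    discrimination threshold and integration window under varying top-down
    feedback.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
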