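Package: dcmnet
Title: Delayed-Correlations Matching Plasticity in Stochastic Attractor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for stochastic binary recurrent neural networks
    with asymmetric synaptic couplings under discrete-time synchronous Glauber
    dynamics. Implements the delayed-correlations matching (DCM) synaptic
    plasticity rule, in which each synapse is updated by the difference of
    time-delayed pre/post activity correlations recorded at two successive
    external-field intensities of a staircase stimulus protocol, together with
    classic baselines (Hebb/Hopfield, generalized covariance Hebb, Storkey) and
    an evaluation battery: corruption-and-retrieval storage criterion, maximum
    storage load estimation, spurious-attractor censuses, one-shot palimpsest
    capacity, excitatory-inhibitory (Dale's principle) variants with pluggable
    inhibitory feedback schemes, and a minimal restricted visible-hidden
    extension with a contrastive clamped-limit update.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
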