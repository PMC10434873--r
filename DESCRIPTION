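Package: presynvar
Title: Presynaptic-Variance Plasticity and Population Decoding in a
    Feedforward Orientation-Tuned Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a feedforward rate model of primary visual cortex in
    which a postsynaptic point neuron receives input from a population of
    orientation-tuned (von Mises) presynaptic neurons through synapses that
    are plastic under a rule driven by presynaptic variance alone, or
    alternatively under a classic covariance (Hebbian) rule.  Provides the
    full stimulation protocol (warm-up, random orientation stream, independent
    seeded ensembles), the closed-form equilibrium-weight theory used as an
    analytic oracle, circular-statistics analysis of tuning curves (preferred
    orientation and selectivity from the circular resultant), active-input
    decomposition of the postsynaptic drive, and a decoding harness comparing
    maximum-likelihood and weighted population decoders under Poisson and
    Gaussian response noise, with bias/variance/error evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
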