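Package: breathless
Title: Perceptual Modelling of Breathlessness from CO2 Rebreathing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits and compares Bayesian observer models of breathlessness
    perception to data from hypercapnic rebreathing experiments. An internal
    CO2 concentration is estimated from end-tidal CO2 by a scalar Kalman
    filter with random-walk dynamics; a latent respiratory state evolves from
    the previous breath, is updated by the CO2 estimate with an individual
    sensory weight, and integrates a saturating activity-context effect; a
    linear gain/offset readout maps the state to a 0-100 breathlessness
    rating. Provides per-participant nonlinear least-squares fitting with
    Latin-hypercube multi-start, reduced model variants and a linear
    regression baseline compared by AIC, reduction of raw 50 Hz capnograms to
    per-breath end-tidal values on the 10 s rating grid, and a synthetic
    rebreathing-experiment generator with parameter-recovery and
    model-selection drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
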