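Package: ddmfit
Title: Simulation-Based Inference of Drift-Diffusion Parameters from Swim-Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring latent drift-diffusion (bounded
    Ornstein-Uhlenbeck) parameters from event-based decision data, such as
    swim bouts of larval zebrafish responding to random-dot-motion stimuli.
    Provides a compiled forward-Euler simulator with absorbing bounds,
    partial reset and post-decision delay; extraction and quality control of
    swim events from heading-orientation traces; time-normalized labeled
    inter-swim-interval histograms with a height-weighted Kullback-Leibler
    loss; Bayesian-optimization fitting with a Gaussian-process surrogate;
    and a synthetic-validation suite (model libraries, parameter recovery,
    sensitivity analysis, duration and histogram-noise robustness, bootstrap
    statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
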