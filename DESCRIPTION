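Package: panelmsm
Title: Multi-State Models for Intermittently Observed Longitudinal Data
Version: 0.1.0
Authors@R: person("panelmsm", "developers", role = c("aut", "cre"),
    email = "panelmsm@example.org")
Description: Fits continuous-time Markov multi-state models to panel
    (intermittently observed) longitudinal data.  Supports proportional
    transition intensities with constant, piecewise-constant and Weibull
    baselines, exact and interval-censored transition times, hidden-state
    misclassification (emission) models fitted by the forward algorithm,
    semi-competing risks with an unobservable post-loss-to-follow-up state
    and a sensitivity parameter, expanded state-space joint models for a
    fluctuating ordinal covariate, and clustered progressive processes with
    shared gamma frailties integrated by Gauss-Laguerre quadrature.
    Includes seeded simulators for every model class, maximum-likelihood
    fitting with Wald and likelihood-ratio inference, state-occupancy,
    cumulative-incidence and length-of-stay prediction, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
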