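Package: fracomm
Title: Microbial Community Dynamics with Ecological Memory via Fractional Calculus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates interacting microbial communities whose dynamics carry
    long-term ("ecological") memory, obtained by replacing the first-order
    time derivatives of generalized Lotka-Volterra-family models with Caputo
    fractional derivatives of per-species order.  Provides a fractional
    Adams-Bashforth-Moulton predictor-corrector solver supporting
    incommensurate orders and time-dependent growth rates, community models
    (Hill-type mutual inhibition, pairwise gLV, logistic), pulse, alternating
    and Ornstein-Uhlenbeck growth-rate perturbations, Bray-Curtis-based
    convergence, resistance and resilience metrics, and experiment drivers
    for bifurcation scans, basin-of-attraction sampling and memory sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
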