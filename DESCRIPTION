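Package: bayesrr
Title: Bayesian Relative-Risk Reanalysis of Randomized Trials with Reference and Data-Driven Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Bayesian reanalysis of randomized trials with a binary
    outcome on the relative-risk scale. Builds reference priors (skeptical,
    enthusiastic, minimally informative) and data-driven priors on the log
    relative risk, the latter by hierarchically pooling historical two-arm
    studies with optional down-weighting. Fits a site-adjusted hierarchical
    log-binomial outcome model by MCMC (via 'rjags'), with a closed-form
    conjugate normal oracle for aggregate data, and summarizes posteriors as
    median relative risks, equi-tailed 95 percent credible intervals and
    threshold probabilities such as P(RR < 0.9). Includes a synthetic-data
    generator for multi-site factorial trials and heterogeneous historical
    study pools, plus convergence diagnostics and report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    rjags,
    coda,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
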