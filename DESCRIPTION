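Package: ringsampler
Title: Spike-Coding Networks that Sample, Infer, and Track Head Direction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for spike-coding networks (SCNs)
    that perform Langevin sampling from polynomial exponential-family
    distributions, sampling-based Bayesian inference of stimuli encoded by
    noisy (Poisson, Bernoulli, binomial, geometric) sensory populations, and
    head-direction tracking that combines inference, angular-velocity
    integration, and soft ring-attractor dynamics.  Includes a compiled
    Euler-Maruyama simulation engine, a direct Langevin reference sampler,
    synthetic trajectory and spike-train generators, and analysis routines
    for subthreshold correlations, two-timescale spike correlations, tuning
    curves, bump-velocity statistics, and drift curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
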