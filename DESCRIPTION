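Package: seedlim
Title: Seed and Establishment Limitation Analysis for Seed-Addition Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing seed-addition experiments in plant
    communities. Simulates complete multi-species sowing designs with known
    ground truth; computes realized seed and establishment limitation via
    per-seed recruitment effect sizes; fits nested Beverton-Holt recruitment
    models with negative-binomial error and a plot random effect by maximum
    marginal likelihood (adaptive Gauss-Hermite quadrature) and compares them
    by AIC; decomposes fundamental limitation into seed, density-independent
    and density-dependent components with crossover analysis; and fits
    hierarchical binomial-logit and lognormal-Poisson mixed models by MCMC
    with Gelman-Rubin diagnostics. A reproducible pipeline ties the stages
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
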