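Package: roostSSM
Title: State-Space Modelling of Roost-Count Time Series with Seasonal
    Availability and Cyclone Disturbance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian state-space modelling of monthly roost ("camp")
    counts of highly mobile animals such as flying-foxes, where the
    proportion of the population available to be counted varies
    seasonally and episodic cyclone disturbance perturbs mortality,
    recruitment and roosting behaviour. Provides the hierarchical
    log-normal process/observation model, an adaptive Metropolis-within-
    Gibbs sampler with Gelman-Rubin diagnostics, a generative simulator
    for synthetic monitoring datasets, derived trend quantities (yearly
    exponential rate of increase, probability of decline, November
    abundance summaries, forward projections), and a nonparametric
    drift-diffusion-jump early-warning analysis for localizing
    perturbations in monitoring series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
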