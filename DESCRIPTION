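Package: dlsdyn
Title: Density-Linked Stochasticity in Discrete Population Dynamics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Beta-binomial state-space models for annual census counts of
    sessile populations sampled as occupied units out of a fixed number of
    sample points. Implements modified Ricker and Hassell mean maps with
    immigration into unoccupied space, constant-variance and
    density-linked overdispersion models, and a disturbance mixture with
    abundance-dependent disturbance probability. Provides maximum
    likelihood fitting with multistart optimization, AIC-based model
    comparison and model averaging, nonparametric diagnosis of the order
    of density dependence by cross-validation, forward simulation,
    deterministic attractor analysis, Monte-Carlo prediction envelopes,
    and ensemble power spectra, together with a synthetic study generator
    shaped like a 16-plot, 18-year intertidal mussel census.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    lhs,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: TimeCourse, Regression, Software
RoxygenNote: 7.3.3
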