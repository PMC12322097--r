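Package: mctchoice
Title: Discrete Choice Experiment Analysis of Preferences for Multi-Cancer Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and estimation toolkit for stated-preference
    studies of multi-cancer early detection tests. Generates blocked Bayesian
    D-efficient choice designs (including split designs where respondent arms
    see overlapping attribute sets), simulates stated choices from known
    preference parameters, estimates pooled mixed multinomial logit models by
    simulated maximum likelihood with data-source scale parameters, sample
    weights and group interactions, fits Integrated Choice and Latent Variable
    (ICLV) models linking cancer knowledge and experience to test preferences,
    and post-processes fits into odds ratios with Krinsky-Robb intervals,
    NPV/PPV marginal rates of substitution with delta-method intervals, and
    exhaustive preference rankings of candidate tests against a benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
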