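Package: longrrm
Title: Random Regression Genetic Evaluation of Longevity with Censored and
    Penalized Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to study how censored and penalty-augmented culling records
    affect random regression genetic evaluation of beef-cattle longevity.
    Provides simulation of multi-generation pedigrees and discrete-time cow
    culling/calving histories, binary trait coding of traditional and
    functional longevity over ages 2-15, nested record-censoring schemes with
    three penalty-method augmentation criteria and two experimental designs,
    Legendre-polynomial random regression animal models fitted either by
    sparse mixed-model equations (BLUP) or by a Gibbs sampler with inverted
    Wishart variance-component updates, age-specific heritability and
    breeding-value trajectories, MCMC convergence diagnostics, and
    scenario-comparison statistics (commonly selected proportions, EBV
    correlations, paired t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
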