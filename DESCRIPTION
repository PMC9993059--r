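Package: erurn
Title: Expectation-Reinforcement Estimation of Bivariate Survival from
    Left-Truncated Right-Censored Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric Bayesian estimation of bivariate survival
    distributions on the integer grid from left-truncated right-censored
    (LTRC) paired lifetimes.  The joint law of a pair (X, Y) is modelled
    with a one-factor latent convolution X = A + B, Y = A + C, each latent
    component carrying a reinforced-urn (discrete beta-Stacy) prior.  The
    expectation-reinforcement (ER) algorithm alternates an EM expectation
    step over the latent components and the truncation variables with a
    reinforcement step that blends the maximum-likelihood urn configuration
    with the prior urns.  Also provides the univariate reinforced-urn
    posterior, the LTRC product-limit (Kaplan-Meier/Lynden-Bell) estimator,
    a rejection-sampling LTRC simulator, a computable bound on the error
    from truncating the infinite supports, and Gompertz/Frank-copula
    reference models for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
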