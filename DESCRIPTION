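Package: gsloss
Title: Bayesian Decision-Theoretic Loss Functions for Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidates for selection in plant and animal breeding by
    posterior expected loss instead of point predictions of breeding values.
    Implements univariate loss functions (Kullback-Leibler divergence between
    the candidate distribution and the truncated parental distribution,
    Continuous Ranked Probability Score, asymmetric linear-linear loss) and
    their multivariate generalizations (multivariate Kullback-Leibler, Energy
    Score, Multivariate Asymmetric Loss Function), all expressible in terms of
    selection intensity and heritability. Includes desk-scale Gibbs samplers
    for Bayesian Ridge Regression and a multi-trait genomic mixed model, the
    truncated-(multivariate-)normal selection-theory quantities the losses
    depend on, and a forward-in-time recurrent-selection simulator that
    benchmarks loss-based selection against standard breeding-value ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
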