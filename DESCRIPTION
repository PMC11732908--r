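Package: adaptlex
Title: Computerized Adaptive Testing for Lexical Decision Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Item response theory engine and computerized adaptive testing
    (CAT) toolkit for two-alternative forced-choice lexical decision tasks.
    Implements the one-parameter logistic model with a fixed lower asymptote
    of 0.5, maximum-likelihood and expected-a-posteriori ability estimation,
    maximum Fisher information item selection with real/pseudoword content
    balancing, marginal maximum likelihood (EM) item calibration, a
    permutation test of item-parameter invariance across groups, Monte Carlo
    and post hoc CAT simulation harnesses, and the evaluation metrics
    (standard error of measurement, empirical reliability, mean squared
    error, bias) used to compare adaptive against random item ordering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
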