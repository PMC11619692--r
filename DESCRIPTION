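Package: lcmgof
Title: Goodness-of-Fit Diagnostics for Diagnostic Latent Class Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how well residual correlation plots and
    chi-squared / likelihood-ratio statistics detect violations of the
    conditional independence assumption in two-class latent class models
    of diagnostic test accuracy without a gold standard. Provides an
    exact simulator for four binary tests with a single conditional
    dependence between tests 1 and 2 in the diseased class, a
    data-augmentation Gibbs sampler for the Bayesian conditional
    independence model with Beta(1,1) priors and the Se + Sp >= 1
    constraint, residual-correlation and overall/pairwise goodness-of-fit
    assessment, and Monte Carlo performance aggregation (bias, coverage,
    detection rates) with exact binomial and MCSE-based intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
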