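Package: corcompare
Title: Correlation-Based Comparison of Polygenic Score Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Formal statistical comparison of the performance of multiple
    polygenic scores against a quantitative outcome in one or more population
    samples, using the joint asymptotic distribution of dependent sample
    correlations. Provides the ANOVA-like within, between and interaction
    hypothesis tests on the stacked vector of score-outcome correlations via
    chi-square contrast statistics, arbitrary user-defined contrasts, pairwise
    difference confidence intervals, nonparametric (bootstrap covariance and
    permutation) variants, and a multivariate-normal simulation engine for
    type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
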