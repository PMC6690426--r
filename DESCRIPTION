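Package: permlogrank
Title: Exact Permutation Log-Rank Tests for Multi-Group Survival Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: The K-group conditional log-rank test with both the usual
    chi-square asymptotic p-value and an exact permutation p-value with
    Clopper-Pearson confidence intervals.  Includes plain label permutation,
    a follow-up-conditioned permutation scheme for unequal censoring between
    groups (after Heinze and co-workers), a brute-force enumeration oracle
    for small samples, a synthetic right-censored survival generator, and
    calibration diagnostics (type-I error simulation, null AP distributions,
    and false-positive-rate curves over random small-cluster partitions)
    that expose regimes -- small or imbalanced groups, many clusters, few
    events -- where the chi-square approximation is anti-conservative.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
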