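Package: gxeminp
Title: Gene-Environment Interaction Scans with Min-P Multiple-Testing
    Adjustment for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing interaction between per-allele SNP effects
    and epidemiological risk factors in pooled multi-study case-control data.
    Fits study-adjusted logistic regression models with multiplicative
    per-allele genotype coding, estimates risk-factor trend effects and
    category-stratified per-allele odds ratios from single joint models, runs
    one-degree-of-freedom product-term interaction scans across a SNP by
    risk-factor grid, and adjusts the resulting family of likelihood-ratio
    p-values for multiple testing by a single-step parametric-bootstrap
    (or within-study permutation) minimum-p procedure. Includes a
    multi-study synthetic case-control cohort generator with configurable
    allele frequencies, risk-factor distributions, main effects and
    interaction effects, and Monte-Carlo power estimation for interaction
    odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
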