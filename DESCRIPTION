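Package: twinace
Title: Multivariate Twin Analysis with Correlated-Factors ACE Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the classical twin design: simulate twin-pair
    phenotype data under a known additive-genetic (A), shared-environment
    (C), nonshared-environment (E) covariance structure; fit constrained
    saturated and correlated-factors ACE models to monozygotic/dizygotic
    pair data by full-information maximum likelihood with missing values;
    compare nested submodels by likelihood-ratio tests and information
    criteria; and decompose phenotypic correlations into genetic and
    environmental shares with profile-likelihood confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
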