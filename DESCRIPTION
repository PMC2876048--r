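Package: gainscore
Title: Growth Standardization and Obesity-Risk-Allele Score Analysis for
    Birth Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genetic associations with infancy and
    childhood growth in birth cohorts. Converts anthropometry to age- and
    sex-standardized SD scores via LMS growth references, builds unweighted
    and weighted obesity-risk-allele scores with Hardy-Weinberg and call-rate
    QC, computes conditional (regression-to-the-mean corrected) infancy
    weight gain and failure-to-thrive flags, and fits cross-sectional and
    random-intercept longitudinal models of score-by-age effects, including
    piecewise infancy/childhood slopes. Ships a synthetic birth-cohort
    generator (reference curves, genotypes, growth trajectories, body
    composition) so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
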