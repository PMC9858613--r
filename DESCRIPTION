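Package: cimap
Title: Conditional Independence Maps for Categorical Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure learning of conditional independence maps (CI-Maps)
    for cohorts of mostly binary clinical variables, as used in studies of
    adverse childhood experiences and emergency-department presentations in
    suicidal crisis. Provides mutual-information and G-test association
    statistics on contingency tables with permutation fallbacks, a
    significance-pruned stable skeleton search with bounded conditioning,
    edge orientation by conditional-probability asymmetry with acyclicity
    enforcement, effect sizes (phi, Cramer's V), a calibrated synthetic
    cohort generator (ground-truth networks with conditional probability
    tables solved to hit target mutual-information edge weights and
    published marginals), descriptive summary tables, and a scripted,
    reproducible report including named follow-up tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
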