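Package: fermentomics
Title: Compositional Multi-Omics Analysis of Fermented-Food Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a compositional multi-omics
    workflow for comparing fermented-food consumers and nonconsumers:
    participant and count-table filtering (including rarefaction and
    exclusion-list removal), differential-abundance ranking by regularized
    multinomial log-linear regression with Q2 baseline evaluation,
    feature-set log-ratio statistics (Welch t, Cohen's D, rank-sum,
    chi-square), a random-feature-set permutation null, longitudinal
    log-ratio stability, and microbe-metabolite cooccurrence estimation by
    low-rank factorization of a conditional-probability matrix with biplot
    ordination. A synthetic-cohort generator with planted ground truth
    (group differentials, subject-level temporal stability, latent
    microbe-metabolite affinities, and one group-enriched metabolite)
    makes every stage testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
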