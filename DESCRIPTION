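Package: iopgrs
Title: Genetic Risk Scores for Intraocular Pressure in Open-Angle Glaucoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and evaluation of additive genetic risk scores (GRS)
    built from intraocular pressure (IOP)-associated variants in primary
    open-angle glaucoma case-control cohorts. Provides unweighted (risk-allele
    count) and weighted (log odds-ratio) scores, standardized-coefficient
    multiple linear regression of IOP and vertical cup-to-disc ratio on the
    score, one-way ANOVA with Bonferroni post hoc comparison of the score
    across control, normal-tension and high-tension glaucoma groups,
    age/sex-adjusted logistic regression, and a score-threshold enrichment
    (relative ratio) analysis with chi-square testing. A calibrated synthetic
    cohort generator emulates the genotype-phenotype structure of a
    quota-sampled clinical case-control study so that every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
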