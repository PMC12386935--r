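Package: agestage
Title: Age-Stage, Two-Sex Life Table Analysis for Insect Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes age-stage, two-sex life table schedules and demographic
    parameters (age-stage survival s_xj, age-specific survival l_x, fecundity
    schedules f_xj/m_x, net reproductive rate R0, intrinsic rate of increase r,
    finite rate lambda, mean generation time T, life expectancy e_xj and
    reproductive value v_xj) from individual-level daily rearing records of
    insect cohorts. Provides bootstrap standard errors and paired bootstrap
    tests for between-cohort comparison, deterministic age-stage population
    projection with bootstrap confidence bands, Quade randomized-block tests
    for bi-choice feeding and oviposition preference assays, and a synthetic
    cohort generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
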