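Package: sleepmr
Title: One-Sample Mendelian Randomization and Survival Analysis of Sleep
    Traits and Cancer Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating causal effects of ordinal sleep traits
    (chronotype, sleep duration, insomnia symptoms) on cancer incidence and
    mortality in biobank-style cohorts. Implements unweighted genetic risk
    scores with allele harmonization, one-sample two-stage Mendelian
    randomization with tiered covariate adjustment, nonlinear Mendelian
    randomization by residual stratification with localized average causal
    effects and formal nonlinearity tests, tiered multivariable Cox
    proportional-hazards models, Kaplan-Meier and covariate-adjusted survival
    curves with log-rank comparison, and a summary-statistic sensitivity
    suite (IVW, MR-Egger, weighted median, radial MR with outlier removal,
    leave-one-out). A synthetic cohort generator with known causal parameters
    supports parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    metafor,
    yaml
Config/testthat/edition: 3
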