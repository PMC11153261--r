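Package: t2dsubgroups
Title: Data-Driven Subgroups of Type 2 Diabetes in Longitudinal Registry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for stratifying individuals with type 2 diabetes into five
    data-driven phenotype subgroups (SIDD, SIRD, MOD, MD, MDH) by
    sex-stratified k-means clustering of five baseline clinical indicators
    (age, BMI, HbA1c, C-peptide, HDL-cholesterol), and for studying what the
    subgroups add over follow-up: windowed re-assessment of membership by
    de novo re-clustering and by nearest-centre reallocation with multi-class
    agreement statistics (accuracy, Cohen's kappa, specific agreement),
    random-intercept trajectory models of clinical parameters, left-truncated
    Cox models and Kaplan-Meier cumulative incidence for diabetes-related
    complications, ATC-code based treatment-step classification with
    multinomial logistic models, and AIC/relative-likelihood comparison of
    discrete subgroups versus the raw clustering indicators as predictors.
    Includes a seeded generator of registry-like synthetic cohorts so the
    whole pipeline is testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    lme4,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
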