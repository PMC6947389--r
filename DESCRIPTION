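Package: gwgtraj
Title: Gestational Weight Gain Classification, Trajectory Modelling and
    Perinatal Risk Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing maternal weight kinetics during pregnancy:
    WHO pre-pregnancy BMI categorisation, trimester-resolved classification of
    gestational weight gain against the Institute of Medicine 2009
    recommendations (with second-to-third trimester transition tables),
    group-based trajectory modelling of weight versus gestational age (finite
    Gaussian mixtures of polynomial mean curves fitted by EM, BIC order
    selection, posterior-probability adequacy diagnostics), relative-risk
    estimation for maternal and neonatal outcomes by modified Poisson
    regression with robust sandwich variance, Cochran-Armitage trend tests and
    group-comparison procedures, and a seeded synthetic perinatal cohort
    generator so the full pipeline is testable without access to clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
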