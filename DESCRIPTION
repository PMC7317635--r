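Package: pamslt
Title: Proportional Multistate Life Table Modelling of Physical Activity
    Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A proportional multistate life table (MSLT) engine for
    estimating the lifetime health gains (quality-adjusted life years),
    health-system cost impacts, and cost-effectiveness of population
    physical-activity interventions.  A closed 2011-style adult population,
    stratified by age, sex and ethnicity, is advanced annually through a
    main all-cause life table and parallel disease life tables (coronary
    heart disease, stroke, type 2 diabetes, colorectal cancer and breast
    cancer) under business-as-usual and intervention scenarios.
    Intervention effects on weekly MVPA MET-minutes are converted into
    lagged population impact fractions that modify disease incidence;
    changed disease flows feed back into all-cause mortality, morbidity,
    disease treatment costs and unrelated health-system costs.  Includes a
    synthetic-data generator with the statistical structure the model
    assumes, a mass-media app-promotion intervention pathway, discounting
    and equity-adjusted analyses, and full probabilistic sensitivity
    analysis (Monte Carlo uncertainty intervals, cost-effectiveness
    acceptability curves and tornado decompositions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
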