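Package: apcmort
Title: Age-Period-Cohort Analysis of Corrected Cancer Mortality Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-run cancer mortality from vital
    registration systems with imperfect cause-of-death coding and coverage.
    Implements the four-step correction of registered breast-cancer deaths
    (partial proportional redistribution of ill-defined causes, proportional
    redistribution of incomplete cancer diagnoses among specified cancers,
    summation, and decade-specific completeness factors), direct age
    standardization against the Segi world standard population, and
    age-period-cohort Poisson modelling with a log link and person-years
    offset, reported through identifiable (estimable) functions: net drift,
    longitudinal age curve, and period and cohort curvature effects as
    relative risks against a reference period and cohort.  A synthetic
    registry generator with known Lexis-surface structure and controllable
    data-quality corruption supports end-to-end validation, and a sequential
    deviance table compares the nested age, age-drift, age-period,
    age-cohort and age-period-cohort sub-models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
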