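Package: oash20
Title: The OASH 20-Condition Chronic Condition Classification Scheme and
    Multimorbidity Indicators
Version: 0.1.0
Authors@R: person("oash20", "maintainers", email = "oash20@example.org",
    role = c("aut", "cre"))
Description: Machine-readable registry of the 20-condition chronic
    condition classification scheme developed by the HHS Office of the
    Assistant Secretary for Health (OASH), with per-data-system code
    mappings for five national data systems (NHIS, NAMCS, MEPS, NIS and
    Medicare claims from CMS). Provides ICD-9-CM and Clinical
    Classifications Software (CCS) code normalization, a coding engine
    that turns claims-like and survey-like records into per-unit
    condition profiles under each data-system dialect, multiple chronic
    condition (MCC) indicator computation (prevalence, condition-count
    distribution, dyad co-occurrence, cross-system coverage), and a
    synthetic multimorbid-population generator (Gaussian-copula
    condition truth, claims emission with coding noise, survey
    self-report misclassification) so every pipeline stage is testable
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
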