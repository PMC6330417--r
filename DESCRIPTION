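Package: disattrib
Title: Attribution of Disability Prevalence to Chronic Diseases with an
    Additive Hazard Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions the prevalence of disability (Global Activity
    Limitation Indicator) into additive, non-negative contributions of
    chronic-condition groups plus a background term, using a weighted
    binomial additive hazard model with a rank-one age-by-disease
    interaction.  Includes direct age standardization, counterfactual
    decomposition of the educational gap in disability into parts due to
    differences in disease prevalence versus disease disabling impact,
    bootstrap confidence intervals, and a synthetic survey-cohort
    generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
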