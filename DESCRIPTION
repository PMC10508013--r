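Package: finprotect
Title: Financial Risk Protection Indicators from Household Survey Microdata
Version: 0.1.0
Authors@R: person("finprotect", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Household-level measurement of financial risk protection in
    health systems: catastrophic health expenditure (CHE) under capacity-to-pay
    and budget-share thresholds, medical impoverishment (MI) against absolute
    (PPP/CPI-converted) and relative poverty lines, survey-weighted incidence
    estimation with confidence intervals, urban-rural and income-quartile
    inequality contrasts with chi-square tests, weighted probit models of
    indicator determinants with robust standard errors and average marginal
    effects, plus a fully specified synthetic household-survey generator with
    known ground-truth incidences for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
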