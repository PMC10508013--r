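# finprotect

Measuring **financial risk protection** in health systems from household
survey microdata.

Two indicators dominate the monitoring of financial protection (the UHC /
SDG 3.8.2 family):

- **Catastrophic health expenditure (CHE)** — a household's out-of-pocket
  (OOP) health spending is *at least* a threshold share of a denominator:

  `CHE = 1[ OOP >= t * D ]`, with either `D = C - F` (total consumption
  minus food, the nonfood "capacity to pay", `t = 0.40`) or `D = C`
  (total consumption, `t = 0.10` or `0.25`).

- **Medical impoverishment (MI)** — a household above a poverty line `z`
  (per capita, per year) that falls below it once OOP is deducted:

  `MI = 1[ C/h >= z ] * 1[ (C - OOP)/h < z ]`, `h` the family size.
  Because `OOP >= 0`, the weighted share of MI households equals the
  difference between the net and gross poverty headcounts.

Poverty lines are the absolute 1.9 and 3.1 USD/person-day lines (2011 USD,
converted with a PPP factor and a CPI factor: `1.9 x 3.52 x 1.13 = 7.56`
local currency units per day) and a relative line at 60% of the weighted
median per-capita consumption.

On top of the flags the package provides survey-weighted incidence with
Kish-style standard errors, urban–rural and income-quartile gap estimates
with Pearson chi-square tests, multi-wave trend tables, and a weighted
probit model of CHE/MI determinants (urban, income quartiles, family size,
log per-capita consumption and food spending, province fixed effects) with
robust sandwich standard errors and average marginal effects. A fully
specified synthetic household-survey generator with known ground-truth
incidences makes every stage testable without access to the
registration-gated national surveys the pipeline is designed around.

## Worked example

```r
library(finprotect)

# a CFPS-like synthetic survey with known DGP
records <- generate_households(synthetic_config(n_households = 50000), seed = 42)
records$quartile <- assign_income_quartiles(records)

flags <- build_flag_table(records,
                          canonical_che_definitions(),
                          canonical_poverty_lines(records))

weighted_incidence(flags$che_nonfood40, flags$weight)
#>   estimate std_error   ci_low  ci_high     n weighted_n
#> 1 14.71911 0.1794701 14.36735 15.07087 50000      50000

flags$residency <- ifelse(flags$urban == 1, "urban", "rural")
g <- subgroup_gap(flags, "che_nonfood40", "residency", c("rural", "urban"))
g$gap_pp                       # rural - urban, percentage points
#> [1] 11.25485
g$stars
#> [1] "***"

fit <- fit_determinants(records, flags$che_nonfood40)
head(fit$ame[, c("term", "ame", "robust_se", "stars")], 7)
#>          term         ame   robust_se stars
#> 1       urban -0.04105045 0.003220113   ***
#> 2          Q2 -0.02407790 0.004853656   ***
#> 3          Q3 -0.05060143 0.006489453   ***
#> 4          Q4 -0.08116294 0.008514835   ***
#> 5 family_size -0.03327621 0.001174970   ***
#> 6 log_cons_pc -0.03963119 0.006576851   ***
#> 7 log_food_pc -0.14120642 0.006834733   ***
```

The incidence line reads: 14.7% of households (weighted) meet the
40%-of-capacity-to-pay CHE definition, with a 95% CI of 14.4–15.1%. The
rural–urban gap of 11.2 percentage points is significant at the 1% level.
The marginal effects say, e.g., that urban residency lowers the probability
of CHE by 4.1 percentage points holding the other covariates fixed — the
qualitative pattern (urban, higher income quartiles, larger families and
higher food spending all protective) that real Chinese survey data show.

A full config-driven run (load → validate → rebase → flag → estimate →
regress → report) is `run_pipeline("config.yaml")`; a CLI wrapper with
`simulate | flags | incidence | gaps | trend | probit | run` subcommands is
in `inst/cli/finprotect.R`.

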