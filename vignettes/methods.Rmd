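---
title: "Measuring financial risk protection: models, conventions and the synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring financial risk protection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finprotect)
```

## The indicators

Financial risk protection asks whether paying for health care pushes
households into hardship. Two binary household-level indicators are the
workhorses of this literature.

**Catastrophic health expenditure (CHE).** Out-of-pocket (OOP) health
spending is *at least* a threshold share of the household budget:

$$\mathrm{CHE}_i = \mathbf{1}\!\left[\, \mathrm{OOP}_i \ge t \cdot D_i \,\right],$$

with two denominator conventions: the nonfood *capacity to pay*
$D_i = C_i - F_i$ (total consumption minus food) with $t = 0.40$, and total
consumption $D_i = C_i$ with $t = 0.10$ or $t = 0.25$. The comparator is
$\ge$ ("at least"), so a household exactly at the boundary is flagged.

**Medical impoverishment (MI).** A household above a poverty line $z$
(currency per person per year) on gross consumption, but below it once OOP
is deducted:

$$\mathrm{MI}_i = \mathbf{1}\!\left[\tfrac{C_i}{h_i} \ge z\right]\cdot
  \mathbf{1}\!\left[\tfrac{C_i-\mathrm{OOP}_i}{h_i} < z\right],$$

$h_i$ the family size. Poverty uses the opposite boundary convention from
CHE: strictly below the line is poor, exactly at the line is not. Since
$\mathrm{OOP}\ge 0$, gross-poor implies net-poor, and the weighted MI share
equals the net-minus-gross headcount difference exactly — an identity the
test suite asserts to $10^{-12}$ on random tables rather than assumes.

### Degenerate denominators

Raw survey data contain households whose reported food spending exceeds
total consumption. Such records are kept (removal would bias incidence) and
flagged; their capacity to pay is $\le 0$. The classification rule is then:
any positive OOP is catastrophic (a household with no margin above
subsistence that pays anything at all), and zero OOP never is, under any
definition.

### Poverty lines

Absolute lines start from a base in USD per person-day (1.9 or 3.1, in 2011
USD) and convert to local currency of the analysis year via a
purchasing-power-parity factor and a CPI inflation factor:
$1.9 \times 3.52 \times 1.13 = 7.56$ per day, $3.1 \times 3.52 \times 1.13
= 12.33$ per day. Annualization multiplies by `days_per_year = 365`,
giving 2758.47 and 4500.65 per person-year. Published annual figures of
2757.46 and 4499.01 circulate for these same daily values; they differ from
daily $\times 365$ by about 1 currency unit and are not reproducible from
their own stated inputs, so this package derives the annual value from the
daily one and documents the discrepancy instead of hard-coding either
printed figure. The relative line is 60% of the weighted median per-capita
consumption; the median is taken over *households* (the unit of analysis
throughout) with survey weights, using the lower-weighted-median
convention: the smallest observed value whose cumulative weight reaches
half the total. The same lower convention drives the quartile cut-points.

## Estimation conventions

**Weighted incidence.** $\hat p = \sum w_i f_i / \sum w_i$, reported in
percent. The standard error is the weighted-proportion (Kish-style) form
$\mathrm{SE} = \sqrt{\hat p(1-\hat p)\sum w_i^2 / (\sum w_i)^2}$, which
collapses to the binomial SE under equal weights. No strata/PSU design
effect is applied — only cross-sectional weights are assumed available —
and the 95% CI is $\hat p \pm 1.96\,\mathrm{SE}$ truncated to $[0,100]$;
with thousands of households the normal multiplier is indistinguishable
from a $t$ quantile. How the original survey CIs were linearized is not
knowable from published tables; this is a documented package choice, not an
inference about anyone's code.

**Income quartiles.** Cut-points at the lower weighted 25/50/75% quantiles
of household income per capita; a household joins $Q_k$ when its value lies
in $(c_{k-1}, c_k]$, the lowest group closed below. Ties share the lower
group, so fully degenerate incomes put everyone in Q1 rather than
splitting arbitrarily.

**Chi-square tests.** Subgroup contrasts use Pearson's statistic on the
$G \times 2$ table of weighted counts with weights rescaled to sum to the
unweighted sample size. The rescaling is a first-order correction only: it
stops large weights from inflating the statistic while reducing exactly to
the textbook test under equal weights. A second-order Rao–Scott correction
would need design information (strata, PSUs) that plain cross-sectional
weights do not carry.

**Probit determinants model.** For an indicator $Y_i$:

$$\Pr(Y_i = 1) = \Phi\big(\alpha + \delta_1\,\mathrm{Urban}_i +
\boldsymbol\delta_2'\,\mathbf{Q}_i + \delta_3\, h_i +
\delta_4 \log \tfrac{C_i}{h_i} + \delta_5 \log \tfrac{F_i}{h_i} +
\mathbf{X}_i'\boldsymbol\beta\big),$$

with rural and Q1 as reference groups and province dummies
$\mathbf{X}_i$ (first province reference). Rows with nonpositive
consumption or food per capita fall outside the log domain and are dropped
with a count. The fit maximizes the weight-scaled log-likelihood by
Newton–Raphson with the observed information, stopping at gradient
max-norm $<10^{-6}$ or 200 iterations; weights are normalized to mean 1 so
the robust (sandwich) covariance is on the sample-size scale. Collinear
columns are removed by pivoted QR and reported; a covariate that strictly
separates the outcome raises an error naming it, while quasi-separated
fixed-effect cells (e.g. a small province with only events) are left to the
robust SEs, and an outcome that is constant — as happens in a subgroup cell
with zero events — raises "not estimable" rather than returning a
coefficient. Marginal effects are *average* marginal effects over the
estimation sample (the modern default, rather than effects at the means):
$\overline{\phi(x_i'\hat b)}\,\hat b_j$ for continuous covariates and the
average discrete change $\Phi(x^{(1)}\hat b)-\Phi(x^{(0)}\hat b)$ for
dummies, with delta-method robust SEs. The continuous AME is verified
against a finite-difference derivative of the average predicted
probability to $10^{-6}$, and the equal-weight fit against `glm`'s probit
to $10^{-6}$.

## The synthetic test-bed

Real national household surveys of this kind are registration-gated, so
published incidence tables cannot be reproduced at desk scale. Instead the
package ships a generator whose *data-generating process is fully known*,
making parameter recovery — not table matching — the testable claim.

The DGP, drawn in a fixed order from one seeded stream (province, urban,
family size, income, consumption propensity, Engel noise, care-use,
baseline OOP, shock indicator, shock share) so that single-parameter
changes reuse common random numbers:

1. Province uniform over `n_provinces`; urban with probability `p_urban`
   (0.55); family size $1+\mathrm{Pois}(2.2)$.
2. Log per-capita income normal $(9.65, 0.8)$ plus an urban premium of
   0.45 log points.
3. Consumption = income × rate, rate $=1.2\,\mathrm{logit}^{-1}(z)$,
   $z\sim N(0.7, 0.5)$ — right-skewed spending capped at 120% of income.
4. Food share $=\mathrm{clip}(1.6 - 0.13\log(\text{inc pc}) +
   \varepsilon,\ 0.05,\ 0.95)$, $\varepsilon\sim N(0, 0.06)$: an Engel
   curve, shares falling with income.
5. OOP: with probability `p_zero_oop` (0.20) the household uses no care at
   all — absolute, it spends nothing even in a shock year. Otherwise a
   catastrophic shock hits with probability
   $\mathrm{logit}^{-1}(\mathrm{logit}(p_{\text{shock}}) + r_i)$ and OOP
   becomes a $\mathrm{Beta}(2,6)$ share of total consumption; with no
   shock, OOP is lognormal $(7.8 + r_i,\ 1.3)$ at the household level.
6. Weights lognormal (σ = 0.5), normalized to mean 1.

The *risk index* $r_i = -0.40\,\mathrm{urban}_i - 0.35\,\tilde y_i -
0.50\,\tilde\varepsilon_i$ (standardized log income and Engel residual)
tilts both baseline OOP and shock odds. It encodes better insurance
coverage in cities and among the rich, and better health where food
spending runs above what income predicts. This term matters: without it,
OOP is independent of urban/income/food *conditional on consumption*, so a
determinants probit finds near-zero urban and quartile effects and a
mechanically *positive* food effect (more food shrinks the nonfood
denominator). The gradients real surveys show conditional on consumption —
urban, higher quartiles, larger families and higher food spending all
protective — require the DGP to contain them, and household-level baseline
OOP supplies the family-size gradient mechanically (a fixed health bill
against a budget that scales with members). Defaults were calibrated once
so weighted summary magnitudes land in a realistic range for Chinese
surveys (per-capita consumption ≈ 20,000, food ≈ 5,000, OOP ≈ 1,700–2,000
currency units; CHE at the 40% threshold ≈ 15%) and were not revisited
after acceptance outcomes were first measured.

What a green test does establish: the estimators recover known truth (the
weighted incidence lands within 3 SE of a 200,000-draw Monte-Carlo oracle
in ≥ 99/100 seeded samples; the probit recovers the embedded sign pattern
in ≥ 95/100 replicates at n = 20,000). What it does not: anything about
questionnaire design, recall bias, panel attrition, or the four real
surveys' distinct OOP concepts — the dialect layer records those
differences (monthly food collection, supplements included or not) but
deliberately never reconciles them.

## Numerical and design choices

- **Annualization** of monthly source fields is ×12; no seasonality model.
- **Currency rebasing** multiplies all monetary fields by
  CPI(ref)/CPI(wave); it preserves within-record ratios, so CHE flags are
  invariant to it — asserted, not assumed.
- **Boundary conventions**: CHE uses ≥, poverty uses <. The two indicators
  genuinely differ here and the tests pin both boundaries.
- **Missing data**: complete-case per required field, silently dropped but
  counted in the load report; row counts must reconcile
  (source = loaded + dropped) in the pipeline manifest.
- **Generator OOP precedence**: the never-uses-care draw beats the shock
  draw. The alternative (shocks override non-use) would make
  `p_zero_oop = 1` produce nonzero incidence, which is the less intuitive
  contract for a "no health spending" configuration.
- **2×2 chi-square check**: the frozen oracle value for the equal-weight
  table {{30,70},{10,90}} is 12.5 (hand Pearson formula and
  `chisq.test(correct = FALSE)` agree).

## Limitations

No design-based variance (strata/PSU), no CHE intensity or overshoot
measures, no equivalence scales (plain per-capita division), no
concentration indices or trend inference beyond per-wave estimates, no
clustered SEs or causal identification in the determinants model. The
synthetic generator is cross-sectional: no panel structure or attrition.
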