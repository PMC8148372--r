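---
title: "Methods: cost-effectiveness of two-step blood-pressure screening in dental care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness of two-step blood-pressure screening in dental care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpscreen)
```

## The decision problem

An opportunistic two-step hypertension screening programme measures blood
pressure during routine dental check-ups in previously unscreened adults aged
40–75. Office positives (mean systolic/diastolic ≥ 140/90 mmHg) take a week
of home measurements; home positives (≥ 135/85) are referred to a primary
health-care centre, where repeated measurement establishes the diagnosis — so
the screening arm is assumed to produce no false-positive diagnoses. The
comparator is usual care: opportunistic detection during ordinary health-care
contacts, reaching about 3% of the cohort per the underlying incidence
assumption, a quarter of whom are white-coat false positives.

`bpscreen` evaluates this programme against usual care in two stages:

* a **short-term model** (screening through diagnosis, a few months): cost
  ledgers per arm and the incremental cost per identified case of
  hypertension;
* a **long-term model** (20 years): a six-state Markov cohort model in which
  newly treated hypertensives face lower cardiovascular risk, yielding an
  incremental cost per QALY.

Both are costed from the **payer** perspective (health and dental care) and
the **societal** perspective (payer plus patient time at 160 SEK/hour and
travel at 6.5 SEK/trip). All accounting is in 2019 SEK; euro values divide by
the fixed study rate of 10.3 at reporting time only.

## Parameter registry

Every input lives in one validated registry (`default_parameters()`,
packaged as `table1_baseline.yaml`): cohort composition (2,025 persons; 930
men, 1,095 women; start age 53, the cohort mean of 52.8 rounded to a whole
cycle age), thirteen unit costs, sex-specific 365-day case fatality and
post-event added annual mortality for AMI and stroke, four QALY-weight
decrements, mean systolic blood pressure by status (147 untreated
hypertensive / 140 treated / 131 normotensive), total-cholesterol/HDL ratios
(men 4.0, women 3.2), the screening yield (170 cases, standard error 17) and
the comparator detection assumption (61 diagnosed = 46 true + 15
white-coat), a 20-year horizon and 3% annual discounting of both costs and
QALYs.

## Short-term model

The costing table's arm totals are authoritative. Activity volumes not
printed in the source (primary-care visits, patient hours, trips) are
back-derived once as line total ÷ unit cost and frozen in the packaged
baseline: 812 and 322 primary-care BP visits, 1,012.5 / 1,218 / 4,102
patient-hours (dental, primary care, home measurement), 1,490 / 244 trips.
Two lines absorb small price-rounding inconsistencies in the source so that
the ledger reproduces the published totals to the öre: the diagnosis
work-ups enter as 133,280/785 and 47,824/785 units of the 785 SEK item, and
the fixed programme administration as 165,343/165,000 units of the 165,000
SEK item. The printed *difference* column of the source table is internally
inconsistent with its own arm totals, so differences here are always
computed from arm totals. The incremental cost per identified case divides
the arm cost difference by the 124 additional true positives.

```{r}
st <- short_term_analysis()
st
```

## Long-term model

### States and transitions

Six states: Healthy, AMI-year, Stroke-year, Post-AMI, Post-Stroke, Dead.
Everyone starts Healthy. Each annual cycle, Healthy individuals experience a
first AMI or stroke with Framingham-based probabilities re-evaluated at
their current age, or die of other causes per the life table. The event-year
states resolve into death (sex-specific 365-day case fatality) or the
chronic post-event state, whose annual mortality adds the published excess
risk to background mortality (capped at 1). There are no recurrent or
cross-track events — a person cannot have both an AMI and a stroke — and
death is absorbing.

### Event risks

Annual first-event probabilities come from the parametric Weibull
accelerated-failure-time Framingham functions of Anderson and colleagues
(1991), evaluated at a one-year horizon:
\(p = 1-\exp(-\exp((\log t-\mu)/\sigma))\), with \(\mu\) linear in sex, log
age, log systolic pressure, smoking, log cholesterol ratio, diabetes and
LVH. The registry supplies only systolic pressures (147/140/131), so the
systolic-based published equations are used even though part of the source
text mentions diastolic adjustment. Diabetes was an exclusion criterion of
the screening study, so the diabetic flag is structurally false; smoking and
LVH default to false because no prevalence is reported.

The published coronary endpoint of that model is broad CHD — myocardial
infarction, angina pectoris, coronary insufficiency and coronary death —
whereas the model's event state is an acute MI with acute-care costs and an
MI-specific QALY decrement. The engine therefore multiplies the CHD
first-event probability by the share of first coronary presentations that
are MI in the Framingham cohort, 0.65 for men and 0.50 for women; these are
documented constants of this implementation, not study measurements, and
`annual_event_probability(..., mi_share = c(male = 1, female = 1))` recovers
the raw endpoint. The stroke endpoint is used as published.

### Background mortality

No machine-readable national life table ships with the source, so the
packaged table (`life_table_sweden_synthetic.csv` — *synthetic*, as the name
says) is a Gompertz–Makeham schedule
\(q(x)=a+b e^{\theta x}\) with parameters chosen to approximate recent
Swedish national mortality (men: \(a=5\times10^{-4}\), \(b=1.31\times10^{-5}\),
\(\theta=0.1035\); women: \(a=3\times10^{-4}\), \(b=6.84\times10^{-6}\),
\(\theta=0.1070\)), ages 40–100 with the final-age probability set to 1.
Any table with columns `age, sex, qx` can be substituted via
`load_life_table()`.

### Accrual conventions

* QALY weight of Healthy is 1.0; decrements subtract from it; Dead scores 0.
* Event-year cost and decrement apply in full in the cycle the event state
  is occupied; 365-day deaths occur on leaving that state.
* Cycle-0 accruals are undiscounted; discounting starts at cycle 1.
* No half-cycle correction by default (the convention of annual-cycle
  spreadsheet cohort models); `run_cohort(half_cycle = TRUE)` averages
  start- and end-of-cycle occupancy instead.
* Treated strata accrue the annual drug cost while alive, for all 20 years
  (the arms are assumed not to differ in later case-finding); comparator
  white-coat false positives accrue no long-term drug cost.
* Hypertensive cases split between the sexes in proportion to the cohort
  composition; the subgroup scenarios make the whole 2,025-person cohort
  male or female.

```{r}
run_cea(subgroups = c("all", "men", "women"), perspectives = "payer")
```

## Uncertainty analysis

**Deterministic (tornado).** Each axis is varied one at a time — ±20% for
identified-case prevalence (detection ratios held fixed), AMI, stroke and
drug costs and the AMI/stroke decrements; 10 vs 30 years for the horizon;
0–5% for the discount rate — and the ICER recomputed. The discount rate is
varied here but *not* sampled in the PSA, since the probabilistic analysis
is described over prevalence, costs, transition probabilities and
decrements only.

**Probabilistic.** 5,000 joint draws: gamma for every unit cost, beta for
every scalar probability and decrement, Normal(170, 17) for the screening
yield. A "±20%" range is read as a central 95% interval (sd = 0.2 ×
mean / 1.96), the conventional CEA elicitation when only ranges are
published; beta and gamma parameters are then moment-matched, and an
infeasible beta standard deviation is shrunk to 99% of its feasible maximum
with a warning. The Framingham and life-table risks are functional
(age-varying), so their stated beta uncertainty is implemented as
multiplicative hazard-scale factors with mean 1 and the same ±20% reading,
drawn from a gamma to keep support non-negative. Cohort sizes are fixed.
Draws use one L'Ecuyer-CMRG substream per draw keyed to the master seed, so
draw *i* is reproducible and independent of how many draws are requested.
Cost-effectiveness at willingness-to-pay \(\lambda\) is decided by net
monetary benefit \(\lambda\,\Delta Q-\Delta C>0\); the CEAC default grid
spans 0–3M SEK in 25,000-SEK steps, covering both informal Swedish
thresholds (500,000 and 1M SEK).

```{r, fig.width = 6, fig.height = 4}
draws <- run_psa(n = 500, seed = 1)   # 5,000 in the full analysis
ceac(draws, wtp = c(5e5, 1e6))
plot_ce_plane(draws)
```

## Synthetic cohort and cascade

The generator exists so that every downstream stage can be exercised with
no external data. Ages are truncated-normal (52.8, 8.7) on [40, 75] via
inverse-CDF sampling; undetected hypertension is Bernoulli with prevalence
calibrated so the expected confirmed yield is 170/2,025 = 8% after the
cascade's two-step sensitivity; 25% of normotensives carry a white-coat
office elevation. Office readings are the status mean (147/131) plus
N(0, 4) noise, with a +13 mmHg white-coat elevation at the office only;
home means run 5 mmHg below office level (mirroring the 140 vs 135
thresholds) with N(0, 8.33) noise. The home noise sd is the one tuned
constant: it sets the probability that a white-coat positive also passes the
home step to 0.14, i.e. an 86% false-positive reduction, which together with
the other constants reproduces the referral positive predictive value of
about 0.76. Primary care confirms only true hypertensives. Cascade counts
convert to costing volumes through per-event rates back-derived from the
baseline (0.5 dental hours per person screened; home hours per office
positive; visits, hours and trips per referral). The comparator arm draws
Binomial(n, 3%) diagnoses with a 25% white-coat share.

What the generator does *not* emulate: longitudinal BP trajectories,
treatment adherence, diastolic pressure (thresholds are applied on the
systolic scale only), age- or sex-dependent prevalence, and any correlation
between BP level and cardiovascular risk factors. Tests passing on
synthetic data therefore validate the pipeline's arithmetic and its
operating characteristics in expectation, not the programme's real-world
yield.

```{r}
roster <- generate_cohort(seed = 1)
simulate_screening_cascade(roster, seed = 2)
```

## Numerical and design notes

* Problem sizes: the cohort engine is deterministic and runs in
  milliseconds; the packaged analyses use the study's own sizes (2,025
  persons, 20 cycles, 5,000 PSA draws). Verification against the
  individual-level Monte Carlo oracle in the test suite uses 10^5
  simulated individuals.
* Degenerate inputs: equal case counts yield a tagged `"undefined"` ratio
  rather than an error; a cohort with all risks scaled to zero accrues the
  closed-form annuity; at the life table's final age death takes precedence
  over event risks; otherwise competing Healthy-row probabilities above 1
  raise an error, as they signal bad inputs.
* Ages beyond the risk equations' 30–74 estimation range (reached only
  under the 30-year horizon axis) are clamped to 74 with a warning.
* Money is displayed as whole SEK (ledgers) or rounded to the nearest
  100,000 SEK (long-term results), but all files and returned objects keep
  full precision.

## Known limitations

* The MI share of coronary events and the synthetic life table are this
  implementation's documented approximations; both are exposed so users can
  substitute their own.
* Health consequences are limited to first AMI and stroke — no heart
  failure, renal disease, recurrent events or combined histories — so the
  model inherits the source's conservative scope.
* The female incremental QALY gain in this implementation exceeds the
  published one, and consequently so does the mixed-cohort gain; the
  all-male gain, the ICER level and all orderings agree. The test suite
  records these comparisons at their stated tolerances.
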