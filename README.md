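# bpscreen

Cost-effectiveness analysis of an opportunistic two-step hypertension
screening programme in a dental-care setting, compared with usual care
(no screening).

High blood pressure is the leading modifiable cardiovascular risk factor,
and most adults visit a dentist yearly, which makes dental check-ups a
cheap screening opportunity. The programme modelled here measures office
blood pressure at the dental visit (positive at ≥ 140/90 mmHg), confirms
positives with a week of home measurement (≥ 135/85), and refers confirmed
positives to primary care for diagnosis and treatment. The package is aimed
at health economists and HTA analysts who want a reproducible, testable
implementation of the full evaluation: the short-term cost per identified
case, the long-term cost per QALY, and the uncertainty analyses around
them.

## The model

**Short-term** (screening through diagnosis): per-arm cost ledgers —
health/dental-care lines for the payer perspective, plus patient time and
travel for the societal perspective — and the incremental cost per
identified case,

```
ICER = (Cost_screening − Cost_no_screening) / (Cases_screening − Cases_no_screening)
```

with 170 true positives under screening versus 46 under usual care (124
additional cases among 2,025 screened).

**Long-term** (20 years, annual cycles, 3% discounting of costs and QALYs):
a six-state Markov cohort model — Healthy, AMI-year, Stroke-year, Post-AMI,
Post-Stroke, Dead. Annual first-event risks come from the Anderson (1991)
parametric Framingham equations evaluated at each cycle's age and at the
arm-specific systolic pressure (treated 140 mmHg vs untreated 147 mmHg);
background mortality comes from a bundled synthetic Swedish-style life
table; event states carry 365-day case fatality, post-event states carry
added mortality, and QALY weights are 1 minus the published decrements.
Incremental results are reported per subgroup (all / men / women) and
perspective, with the ICER in SEK per QALY.

**Uncertainty**: a one-way tornado analysis (±20% parameter ranges, 10–30
year horizon, 0–5% discount rate) and a 5,000-draw probabilistic
sensitivity analysis (gamma costs, beta probabilities and decrements,
Normal(170, 17) screening yield) summarised as a cost-effectiveness plane
and acceptability curve under the net-monetary-benefit rule.

A synthetic cohort and screening-cascade generator reproduces the study's
demographics and operating characteristics (8% confirmed yield, 86%
white-coat reduction at the home step) so every stage is testable without
external data.

## Worked example

```r
library(bpscreen)

short_term_analysis()
#> <short_term_results>
#>   payer   : delta cost 595,069 SEK / 124 extra cases = 4,799 SEK per case
#>   societal: delta cost 1,587,088 SEK / 124 extra cases = 12,799 SEK per case

run_cea()
#> <cea_results> incremental cost-effectiveness, screening vs none
#>  subgroup perspective d_cost d_qaly      icer    tag
#>       all       payer   4.3M   2.26 1.9M/QALY normal
#>       all    societal   5.3M   2.26 2.3M/QALY normal
#>       men       payer   4.2M   3.13 1.3M/QALY normal
#>       men    societal   5.1M   3.13 1.6M/QALY normal
#>     women       payer   4.4M   1.52 2.9M/QALY normal
#>     women    societal   5.4M   1.52 3.5M/QALY normal
```

Reading this: screening an unscreened 2,025-person cohort costs an extra
595,069 SEK (payer) over the diagnosis period — about 4,800 SEK per newly
identified hypertensive (12,800 SEK when patient time and travel are
counted). Over 20 years the additional treatment averts a fraction of first
AMIs and strokes, gaining ≈ 2.3 discounted QALYs for the cohort at ≈ 1.9
million SEK per QALY (payer) — far above the informal Swedish threshold of
500,000 SEK per QALY, so the programme is unlikely to be cost-effective
despite its good detection performance. Men benefit more than women (higher
untreated coronary risk), so the all-male ICER is lowest.

```r
draws <- run_psa(n = 5000, seed = 1)
ce_plane_summary(draws)
#>   NE   NW   SE   SW
#> 5000    0    0    0
ceac(draws, wtp = c(5e5, 1e6))
#>     wtp probability
#> 1 5e+05           0
#> 2 1e+06           0
```

Every PSA draw lands in the north-east quadrant (costlier, more effective),
and no draw is cost-effective at 500,000 SEK per QALY. In the tornado
analysis no single perturbation brings the ICER below that threshold
either; the time horizon dominates (1.1M SEK/QALY at 30 years, 5.4M at 10).

Figures: `plot_tornado(one_way_dsa())`, `plot_ce_plane(draws)`,
`plot_ceac(ceac(draws))`. The whole pipeline, with CSV/JSON artifacts and a
run manifest, is `run_full_analysis(out_dir = "results")`; a thin
command-line wrapper lives at `inst/cli/cea.R`.

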