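# bmcea

Brain-metastasis-aware Markov cost-effectiveness modelling for
extensive-stage small-cell lung cancer (ES-SCLC).

## The problem

Adding the immune-checkpoint inhibitor atezolizumab to first-line
platinum–etoposide chemotherapy improves survival in ES-SCLC, but at a high
price, and the benefit concentrates in patients *without* baseline brain
metastases (BM). Conventional three-state oncology models (progression-free
/ progressed / dead) treat progressed disease as homogeneous and miss the
lower utility and higher costs that BM brings. `bmcea` implements a
four-state semi-Markov cohort model that splits progressed disease by BM
status:

```
PF ──TP1──► PD without BM ──TP4──► PD with BM
 │               │TP5                  │TP6
 ├──TP2──────────┼─────────────────────┤
 └──TP3──────────► death ◄─────────────┘
```

Each transition pathway TP1–TP6 carries its own parametric time-to-event
model — exponential, Weibull, Gompertz, log-logistic, log-normal or
generalized gamma — fitted by maximum likelihood to right-censored
clock-reset (time-since-state-entry) sojourn data and selected by AIC/BIC.
The cohort engine duration-expands the progressed-disease states (tunnel
states), so the semi-Markov hazards apply exactly; per-cycle probabilities
come from cumulative-hazard increments apportioned across competing exits,

&nbsp;&nbsp;&nbsp;&nbsp;p<sub>k</sub>(d) = (ΔH<sub>k</sub>/ΔH)(1 − e<sup>−ΔH</sup>),&nbsp;&nbsp;ΔH<sub>k</sub> = H<sub>k</sub>((d+1)Δ) − H<sub>k</sub>(dΔ).

Outcomes are discounted QALYs, life-years and costs per arm over 3-week
cycles; the decision summaries are the ICER (ΔC/ΔE) and the incremental net
monetary benefit INMB = λ·ΔE − ΔC at the Taiwanese willingness-to-pay
threshold λ = NT$3,023,055 per QALY (3× 2023 GDP per capita).
Progression-free utility is response-weighted and adverse-event-adjusted
per cycle, estimated from longitudinal EQ-5D-3L panels by generalized
estimating equations; medication costs are weighted by the on-treatment
proportion. Decision uncertainty is quantified by one-way deterministic
sensitivity analysis (tornado), probabilistic sensitivity analysis
(cost-effectiveness plane, acceptability curve), per-person expected value
of perfect information, and a nine-scenario framework (alternative survival
families, horizons, progressed-disease utilities).

Because the underlying trial and claims data are access-restricted, the
package ships a synthetic individual-patient-data generator
(`simulate_cohort()`) with known ground truth, used throughout the test
suite; the shipped base-case parameters are synthetic and labelled as such.

## Worked example

```r
library(bmcea)

params <- default_params()        # synthetic base case, published constants
res <- run_cea(params)
print(res)
```

```
Two-arm Markov cost-effectiveness result (15-year horizon)
  intervention  cost 1,973,808  QALY 0.952  LY 1.262
  comparator    cost 1,040,375  QALY 0.631  LY 0.839
Incremental cost-effectiveness summary (NT$)
  ΔCost  933,433
  ΔQALY  0.320   ΔLY  0.423
  ICER   2,912,886 per QALY
  ICER   2,205,285 per LY
  INMB   35,304 per QALY (WTP 3,023,055)
  INMB   346,138 per LY
  quadrant NE
```

The intervention buys 0.320 QALYs for NT$933,433 extra — north-east
quadrant, ICER just under the willingness-to-pay threshold, hence a small
positive INMB: cost-effective, but sensitive to assumptions. Quantify that:

```r
psa <- run_psa(params, n_draws = 5000, seed = 1)
print(psa)                        # P(cost-effective), quadrant shares, EVPI
plot(psa, "ceac")

dsa <- one_way_dsa(params)
plot(dsa)                         # tornado diagram

run_scenarios(params, psa_draws = 1000)
```

Fitting your own transition models from clock-reset sojourn data:

```r
d <- read_transition_data("transitions.csv")   # id, arm, transition_id,
tp1 <- d[d$transition_id == "TP1" & d$arm == "comparator", ]
fits <- fit_all_families(tp1)
select_models(fits)$table                      # AIC/BIC ranking
```

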