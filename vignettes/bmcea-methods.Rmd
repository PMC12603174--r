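---
title: "Methods: a brain-metastasis-aware semi-Markov cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a brain-metastasis-aware semi-Markov cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`bmcea` evaluates atezolizumab plus platinum–etoposide chemotherapy against
chemotherapy alone for extensive-stage small-cell lung cancer without
baseline brain metastases (BM), from a single-payer perspective in 2023
New Taiwan dollars. Four health states: progression-free (PF), progressed
disease without BM, progressed disease with BM, and death. Six transition
pathways connect them (TP1: PF→PD without BM, TP2: PF→PD with BM, TP3:
PF→death, TP4: PD without BM→PD with BM, TP5: PD without BM→death, TP6:
PD with BM→death); no reverse flows exist. The cohort starts entirely in
PF and is propagated over 3-week cycles to a 15-year horizon, with costs
and health outcomes discounted at 3% per year and a willingness-to-pay
threshold of NT$3,023,055 per QALY (three times 2023 GDP per capita).

### Clock-reset hazards and tunnel states

Transition hazards are *semi-Markov*: they depend on time since entry into
the current state, not model time. Six parametric families are supported
per pathway and arm — exponential, Weibull, Gompertz, log-logistic,
log-normal, generalized gamma — in the parameterizations dominant in
multistate survival fitting, so published coefficient tables transcribe
directly:

| family | parameters | convention |
|---|---|---|
| exponential | rate | $S(t)=e^{-\lambda t}$ |
| Weibull | shape, scale | $S(t)=\exp(-(t/\sigma)^k)$ |
| Gompertz | shape, rate | $H(t)=\frac{\lambda}{a}(e^{at}-1)$, $a$ may be negative |
| log-logistic | shape, scale | $S(t)=1/(1+(t/\sigma)^k)$ |
| log-normal | meanlog, sdlog | normal on $\log t$ |
| generalized gamma | $\mu,\sigma,Q$ | $Q\to0$ log-normal, $Q=1$ Weibull |

Positive-constrained parameters are carried on the log scale for fitting
and probabilistic analysis. A negative Gompertz shape implies a hazard
plateau and a non-vanishing $S(\infty)$; the engine and the data generator
both treat "never exits" as administrative censoring rather than an error.

Because PF is entered only at time zero, PF duration equals model time and
a scalar suffices. The two PD states are *duration-expanded* (tunnel
states): occupancy is tracked per completed cycle in state, so clock-reset
hazards apply exactly rather than approximately. Memory is linear and work
quadratic in the number of cycles — negligible at 3-week cycles even over
40 years.

### Per-cycle transition probabilities

Within a cycle of length $\Delta$ starting at state-age $u=d\Delta$, each
competing exit $k$ contributes a cumulative-hazard increment
$\Delta H_k = H_k(u+\Delta)-H_k(u)$. The engine treats cause-specific
hazards as piecewise-constant within the cycle:

$$p_k(d) = \frac{\Delta H_k}{\Delta H}\bigl(1-e^{-\Delta H}\bigr),
\qquad \Delta H = \sum_k \Delta H_k,$$

with all $p_k=0$ when $\Delta H=0$. The stay probability $e^{-\Delta H}$
equals the exact sojourn-survival ratio $S(u+\Delta)/S(u)$ for any family;
only the split *among* causes is approximate (exact for exponentials,
$O(\Delta^2)$ otherwise). A refinement property test verifies that halving
the cycle reproduces composed exit probabilities to $10^{-6}$.

Consequences of discreteness worth knowing: a patient cannot progress and
die within the same cycle, so state occupancy lags continuous time by
$O(\Delta)$, most visibly in early death occupancy when post-progression
hazards are high. The package's end-to-end consistency oracle (empirical
occupancy of 20,000 simulated patients versus the analytic trace) therefore
runs at 7-day cycles, where that discretization error is subdominant to the
oracle's 0.02 tolerance; the refinement property test covers the
discretization behaviour itself.

### Rewards and half-cycle correction

Per-cycle PF utility is response-weighted and adverse-event-adjusted:

$$u_{PF}(c) = u_{pre} + (u_{post}-u_{pre})\,r(c) + \sum_g a_g(c)\, d_g,$$

where $r(c)$ is the proportion responding by cycle $c$, $a_g(c)$ the
prevalence of active grade-3+ adverse events in category $g$ (leukocyte
deficiency, anemia, platelet deficiency) and $d_g \le 0$ the fitted
disutilities. Defaults: $u_{pre}=0.74$, $u_{post}=0.81$, PD utilities 0.76
(no BM) and 0.72 (BM), disutilities −0.0005, −0.0124, −0.0692.

Costs per PF cycle: chemotherapy over the four induction cycles, plus
atezolizumab (NT$83,258 per cycle) from cycle 1 until discontinuation,
both weighted by the on-treatment proportion; expected adverse-event
management costs (prevalence × per-event cost); and non-medication
fee-schedule points converted to NT$ by the 0.9198 conversion factor. PD
cycles accrue subsequent-therapy plus converted non-medication costs, with
the BM state allowed higher amounts. A one-off terminal supportive-care
cost attaches to each cycle's new deaths.

Half-cycle correction (default on, configurable) uses the trapezoidal
average of cycle-start and cycle-end occupancy with mid-cycle discounting.
The trapezoid is the substantive part: with left-endpoint occupancy the
engine would overshoot mean survival by about half a cycle, which the
closed-form two-state oracle (LY within 0.5% of $1/\lambda$ over 80 years)
would not forgive. The number of cycles is
$\lfloor \text{horizon}/\Delta \rfloor$; a residual fraction of a cycle is
dropped.

## Estimation components

**Survival fitting.** `fit_transition()` maximizes the right-censored
log-likelihood $\sum_{events}\log f + \sum_{cens}\log S$ via
`flexsurv::flexsurvreg`, which implements exactly these six families in
these parameterizations; the package wraps the result (unconstrained
coefficients, observed-information covariance, log-likelihood) in its own
`surv_model` container. Fits with fewer events than parameters are refused
as degenerate. `select_models()` ranks by $AIC = 2k-2\ell$, breaking exact
ties by fewer parameters then fixed family order, and reports
$BIC = k\log n - 2\ell$ alongside; visual assessment is supported by
`plot_fit_report()` (Kaplan–Meier overlay) but never drives selection.

**GEE utility model.** Repeated per-cycle EQ-5D-3L utilities are clustered
by patient. `fit_gee()` solves the gaussian identity-link estimating
equations with an independence or exchangeable (default) working
correlation, implemented directly in the package, with cluster-robust
sandwich covariance. With one record per cluster or independence working
correlation it reduces exactly to ordinary least squares, which the test
suite exploits as an oracle; a score-at-solution check (‖score‖ < 1e−8)
guards convergence. The design matrix is configurable; the default is
intercept + response + three adverse-event indicators.

**Time-varying curves.** `curves_from_ipd()` builds, per cycle:
response proportion among at-risk patients; adverse-event prevalence per
category (episodes below grade 3 ignored; categories with ≤2% patient
incidence zeroed; overlapping episodes counted once); and the on-treatment
proportion as a Kaplan–Meier estimate of discontinuation with
administrative censoring. Tails beyond follow-up hold the last at-risk
value (response, prevalence) and drop to zero (on-treatment), both
configurable.

## Uncertainty analysis

Deterministic bounds: survival coefficients ±1.96 SE on the unconstrained
scale (one coefficient at a time), the conversion factor over its supplied
regional (min, max), everything else ±25% (utilities capped at 1). The
tornado orders parameters by descending INMB range; a model failure at a
bound flags the row instead of dropping it.

Probabilistic distributions are conventional CEA practice, flagged as
assumptions in the run manifest because the source analysis does not state
its choices: beta for utilities and proportions (method of moments, SE =
10% of base, truncated to validity), gamma for costs (SE = 25% of base),
negated gamma for disutilities, multivariate normal per transition on the
unconstrained coefficient scale using the fit covariance. The
willingness-to-pay threshold varies in the deterministic analysis only.
Each parameter draws from its own substream, seeded deterministically from
the master seed and the parameter's name, so adding or removing one
parameter never shuffles the others. CEAC values are draw fractions with
positive net benefit; per-person EVPI is
$E_\theta[\max_s NMB_s] - \max_s E_\theta[NMB_s] \ge 0$.

**Scenarios.** 1: each transition's second-best fit by AIC (BIC
tie-break). 2–3: among each transition's three lowest-AIC candidates, the
family with the largest (optimistic) or smallest (pessimistic) survival at
the model horizon. "Favorable" is interpreted uniformly per transition as
the longest sojourn in the healthier origin state; for transitions into
death this is literally the most favorable long-term survival, and for
progression transitions delayed progression keeps patients in the better
state, so the same rule applies. 4–7: horizons of 5, 10, 20 and 40 years
(20 years covers over 99% of deaths; 40 addresses younger patients). 8–9:
both PD utilities set to 0.7511 (all-participant estimate) or 0.473
(earlier literature). Scenario application is a pure transformation of a
copied parameter set; survival scenarios never touch rewards or costs.

## The synthetic cohort generator

Real individual-patient data (trial IPD via a data-sharing platform,
claims-based costs under national license) are access-restricted, so
`simulate_cohort()` generates trial-like data with known ground truth:
multistate event histories drawn by total-hazard inversion (sojourn solves
$H_{tot}(s)=E$, $E\sim$ Exp(1), cause apportioned by hazard ratio at the
event time — exact for this model class, no latent-failure-time
assumption), administrative censoring over an accrual-like window (1.2 to
2.2 years), response onsets, treatment discontinuation, Poisson
adverse-event episodes with log-normal durations and categorical grades
(including sub-threshold grade-2 episodes so the inclusion filter has work
to do), and a per-cycle utility panel with patient random intercepts
(SD 0.05) and residual noise (SD 0.08), clamped to the instrument range
[−0.594, 1].

The default generator truth equals the shipped base-case transition
models; 201/202 patients per arm. The shipped base case itself is
*synthetic*: published constants are used wherever they exist (utilities,
disutilities, atezolizumab price, conversion factor, discounting, cycle
length, horizon, threshold, arm sizes), while transition parameters, cost
amounts and curves — which are not published — were chosen once to be
clinically plausible for ES-SCLC (median PFS around five months, short
post-progression survival, shorter with BM) and to place the base case in
the north-east quadrant near the threshold, qualitatively matching the
decision problem. Passing tests therefore demonstrate the machinery's
correctness on data of this structure, not reproduction of the restricted
trial's numbers: real data would add covariate-driven heterogeneity,
informative censoring, measurement error in progression dates and
utilities, and none of these are emulated.

## Numerical choices and test scale

Root solves (sojourn inversion) use `uniroot` at 1e−9 tolerance; cycle
probabilities clamp tiny negative hazard increments to zero and abort
with a named transition and time on non-finite increments (Gompertz
overflow). Currency is displayed as integer NT$ and effects to three
decimals; internal arithmetic is unrounded. The test suite sizes its
simulations to what the checks need: 20,000 patients for the occupancy
oracle, 500 per dataset (10 replicates for the weakly-identified Gompertz)
for maximum-likelihood recovery, 400 patients for GEE recovery with
simultaneous (Bonferroni + joint Wald) coverage, 5,000 draws × two seeds
for Monte-Carlo stability of the acceptability probability.

## Limitations

The engine is a cohort model: no patient-level heterogeneity beyond the
duration expansion, adverse events enter through rewards rather than as
states, and within-cycle cause apportionment is first-order. Spline or
cure-fraction survival models, covariate-adjusted hazards, left
truncation, clock-forward PD hazards, population-level EVPI and partial
EVPI are out of scope. The EQ-5D-5L→3L mapping is consumed, not
implemented: utility inputs are assumed already on the 3L value scale.
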