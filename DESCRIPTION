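Package: bmcea
Title: Brain-Metastasis-Aware Markov Cost-Effectiveness Modelling for
    Extensive-Stage Small-Cell Lung Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-state semi-Markov (clock-reset) cohort model for the
    cost-effectiveness of atezolizumab plus platinum-etoposide chemotherapy
    versus chemotherapy alone in extensive-stage small-cell lung cancer,
    with progressed disease split by brain-metastasis status. Provides
    parametric multistate survival extrapolation over six standard
    time-to-event families with AIC/BIC model selection, tunnel-expanded
    cohort simulation with time-varying response-weighted utilities and
    adverse-event disutilities, cost accrual with treatment-discontinuation
    weighting, ICER and net-monetary-benefit summaries, deterministic and
    probabilistic sensitivity analysis (tornado, cost-effectiveness plane,
    acceptability curve, expected value of perfect information), a
    nine-scenario framework, generalized-estimating-equation utility
    estimation from longitudinal EQ-5D panels, and a synthetic
    individual-patient-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
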