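# Minimal reward schedule for engine-level checks.
flat_rewards <- function(u = 1, cost = 0, terminal = 0) {
  list(u_pf = u, u_pd_nobm = u, u_pd_bm = u, cost_pf_med = cost,
       cost_pf_other = 0, cost_pd_nobm = cost, cost_pd_bm = cost,
       cost_terminal = terminal)
}

zero_hazard_models <- function() {
  lapply(setNames(paste0("TP", 1:6), paste0("TP", 1:6)),
         function(i) surv_model("exponential", c(rate = 1e-12)))
}

test_that("a cohort with no exits accrues exactly its clock", {
  cfg <- cea_config(cycle_length_days = 36.525, horizon_years = 1,
                    discount_annual = 0, wtp = 1)
  s <- build_schedule(zero_hazard_models(), cfg$n_cycles, cfg$cycle_len)
  tr <- run_cohort(s, flat_rewards(u = 1, cost = 100), cfg)
  expect_equal(tr$ly, 1, tolerance = 1e-9)
  expect_equal(tr$qaly, 1, tolerance = 1e-9)
  expect_equal(tr$cost, 100 * cfg$n_cycles, tolerance = 1e-9)
  expect_equal(unname(tr$occupancy[nrow(tr$occupancy), "PF"]), 1)
})

test_that("mean survival of an exponential two-state model is 1/rate", {
  lambda <- 0.5
  cfg <- cea_config(horizon_years = 80, discount_annual = 0, wtp = 1,
                    half_cycle_correction = TRUE)
  models <- zero_hazard_models()
  models$TP3 <- surv_model("exponential", c(rate = lambda))
  s <- build_schedule(models, cfg$n_cycles, cfg$cycle_len)
  tr <- run_cohort(s, flat_rewards(), cfg)
  expect_lt(abs(tr$ly - 1 / lambda) / (1 / lambda), 0.005)
})

test_that("discounting reproduces the continuous-time integral", {
  # constant PF occupancy, utility 1, r = 3%: QALY ~ integral of 1.03^-t
  cfg <- cea_config(cycle_length_days = 3.6525, horizon_years = 1,
                    discount_annual = 0.03, wtp = 1)
  s <- build_schedule(zero_hazard_models(), cfg$n_cycles, cfg$cycle_len)
  tr <- run_cohort(s, flat_rewards(), cfg)
  expect_equal(tr$qaly, (1 - 1.03^-1) / log(1.03), tolerance = 1e-3)
  expect_equal(tr$qaly, 0.98534, tolerance = 1e-3)
})

test_that("mass is conserved, death is monotone and QALY <= LY", {
  p <- small_params()
  cfg <- p$config
  for (arm in c("intervention", "comparator")) {
    s <- build_schedule(p$survival[[arm]], cfg$n_cycles, cfg$cycle_len)
    tr <- run_cohort(s, build_rewards(p, arm), cfg)
    expect_equal(unname(rowSums(tr$occupancy)),
                 rep(1, nrow(tr$occupancy)), tolerance = 1e-12)
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-15))
    expect_true(all(tr$occupancy >= -1e-15))
    expect_lte(tr$qaly, tr$ly)
    expect_true(all(is.finite(c(tr$qaly, tr$ly, tr$cost))))
    expect_equal(sum(tr$new_deaths),
                 unname(tr$occupancy[nrow(tr$occupancy), "death"]),
                 tolerance = 1e-12)
  }
})

test_that("terminal supportive-care cost follows new deaths", {
  cfg <- cea_config(horizon_years = 30, discount_annual = 0, wtp = 1)
  models <- zero_hazard_models()
  models$TP3 <- surv_model("exponential", c(rate = 1))
  s <- build_schedule(models, cfg$n_cycles, cfg$cycle_len)
  tr <- run_cohort(s, flat_rewards(terminal = 1000), cfg)
  # essentially everyone dies within 30 years
  expect_equal(tr$cost, 1000, tolerance = 1e-6)
  expect_equal(unname(tr$cost_components["terminal"]), tr$cost)
})

test_that("identical arms yield zero increments", {
  p <- small_params()
  p$survival$intervention <- p$survival$comparator
  p$curves$intervention <- p$curves$comparator
  cfg <- p$config
  s <- build_schedule(p$survival$comparator, cfg$n_cycles, cfg$cycle_len)
  r <- build_rewards(p, "comparator")
  tr <- run_cohort(s, r, cfg)
  inc <- compare_arms(tr, tr)
  expect_equal(inc$delta_cost, 0)
  expect_equal(inc$delta_qaly, 0)
  expect_equal(inc$delta_ly, 0)
})

test_that("uniformly higher death hazards reduce life expectancy", {
  p <- small_params()
  worse <- p$survival$comparator
  for (tp in c("TP3", "TP5", "TP6")) {
    m <- worse[[tp]]
    prm <- m$params
    if (m$family == "exponential") prm["rate"] <- prm["rate"] * 1.5
    else prm["scale"] <- prm["scale"] / 1.3
    worse[[tp]] <- surv_model(m$family, prm)
  }
  cfg <- p$config
  s1 <- build_schedule(p$survival$comparator, cfg$n_cycles, cfg$cycle_len)
  s2 <- build_schedule(worse, cfg$n_cycles, cfg$cycle_len)
  r <- build_rewards(p, "comparator")
  inc <- compare_arms(run_cohort(s1, r, cfg), run_cohort(s2, r, cfg))
  expect_gt(inc$delta_ly, 0)
})

test_that("merging the PD states leaves results invariant to the BM split", {
  # equal PD utilities and costs: scaling the PD_noBM -> PD_BM pathway must
  # not change outcomes while total exit-to-death hazards are preserved.
  # The discrete model allows one transition per cycle, so the equivalence
  # holds up to O(cycle^2) per cycle; a 7-day cycle keeps that below 0.5%.
  p <- small_params(cycle_length_days = 7)
  p$utilities$u_pd_bm <- p$utilities$u_pd_nobm
  p$costs$pd_bm_med <- p$costs$pd_nobm_med
  p$costs$pd_bm_nonmed_points <- p$costs$pd_nobm_nonmed_points
  # same memoryless death hazard from both PD states, so the clock reset on
  # entering PD_BM cannot matter and the merged state is Markov
  p$survival$comparator$TP5 <- surv_model("exponential", c(rate = 0.9))
  p$survival$comparator$TP6 <- surv_model("exponential", c(rate = 0.9))
  base <- p$survival$comparator
  alt <- base
  alt$TP4 <- surv_model("weibull", c(shape = 1.1, scale = 0.4))  # faster BM
  cfg <- p$config
  r <- build_rewards(p, "comparator")
  tr1 <- run_cohort(build_schedule(base, cfg$n_cycles, cfg$cycle_len), r, cfg)
  tr2 <- run_cohort(build_schedule(alt, cfg$n_cycles, cfg$cycle_len), r, cfg)
  expect_equal(tr1$qaly, tr2$qaly, tolerance = 5e-3)
  expect_equal(tr1$cost / tr2$cost, 1, tolerance = 5e-3)
})

test_that("mismatched horizons are rejected", {
  p5 <- small_params(5); p10 <- small_params(10)
  r5 <- run_cea(p5, keep_traces = TRUE)
  r10 <- run_cea(p10, keep_traces = TRUE)
  expect_error(compare_arms(r5$traces$intervention,
                            r10$traces$comparator), "horizon")
})
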