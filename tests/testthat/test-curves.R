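cl <- 21 / 365.25

test_that("a single active episode yields unit prevalence in its cycles", {
  fu <- data.frame(id = 1, arm = "comparator", pf_exit_time = 10 * cl)
  ae <- data.frame(id = 1, arm = "comparator", category = "anemia",
                   grade = 3, onset = 1 * cl + 1e-6,
                   resolution = 4 * cl - 1e-6)  # active in cycles 2-4
  resp <- data.frame(id = integer(), arm = character(), time = numeric())
  disc <- data.frame(id = 1, arm = "comparator", time = 10 * cl, event = 0)
  cv <- curves_from_ipd(fu, resp, ae, disc, n_cycles = 8, cycle_len = cl,
                        min_incidence = 0)
  prev <- cv$comparator$ae_prev[, "anemia"]
  expect_equal(prev, c(0, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(cv$comparator$resp, rep(0, 8))
})

test_that("overlapping duplicate episodes are not double counted", {
  fu <- data.frame(id = 1:2, arm = "comparator", pf_exit_time = 6 * cl)
  ae <- data.frame(id = 1, arm = "comparator", category = "platelet",
                   grade = c(3, 4), onset = c(0, cl / 2),
                   resolution = c(2 * cl, 2.5 * cl))
  resp <- data.frame(id = integer(), arm = character(), time = numeric())
  disc <- data.frame(id = 1:2, arm = "comparator", time = 6 * cl, event = 0)
  cv <- curves_from_ipd(fu, resp, ae, disc, n_cycles = 4, cycle_len = cl,
                        min_incidence = 0)
  expect_equal(cv$comparator$ae_prev[, "platelet"], c(0.5, 0.5, 0.5, 0))
})

test_that("grade and incidence filters drop non-qualifying categories", {
  fu <- data.frame(id = 1:100, arm = "comparator", pf_exit_time = 4 * cl)
  # grade-2 episodes only: excluded by the grade filter
  ae <- data.frame(id = 1:50, arm = "comparator", category = "anemia",
                   grade = 2, onset = 0, resolution = 2 * cl)
  # one patient (1% incidence): excluded by the 2% incidence rule
  ae2 <- data.frame(id = 1, arm = "comparator", category = "platelet",
                    grade = 4, onset = 0, resolution = 2 * cl)
  resp <- data.frame(id = integer(), arm = character(), time = numeric())
  disc <- data.frame(id = 1:100, arm = "comparator", time = 4 * cl,
                     event = 0)
  cv <- curves_from_ipd(fu, resp, rbind(ae, ae2), disc, n_cycles = 4,
                        cycle_len = cl)
  expect_true(all(cv$comparator$ae_prev == 0))
})

test_that("no discontinuations means full on-treatment proportion", {
  fu <- data.frame(id = 1:5, arm = "intervention", pf_exit_time = 1)
  resp <- data.frame(id = integer(), arm = character(), time = numeric())
  ae <- data.frame(id = integer(), arm = character(), category = character(),
                   grade = integer(), onset = numeric(),
                   resolution = numeric())
  disc <- data.frame(id = 1:5, arm = "intervention", time = 1, event = 0)
  cv <- curves_from_ipd(fu, resp, ae, disc, n_cycles = 10, cycle_len = cl)
  expect_equal(cv$intervention$on_treat, rep(1, 10))
})

test_that("response curves count at-risk patients past onset", {
  fu <- data.frame(id = 1:4, arm = "comparator",
                   pf_exit_time = c(10, 10, 10, 1.5 * cl) * cl)
  fu$pf_exit_time[4] <- 1.5 * cl
  resp <- data.frame(id = c(1, 2), arm = "comparator",
                     time = c(0.5 * cl, 2.5 * cl))
  ae <- data.frame(id = integer(), arm = character(), category = character(),
                   grade = integer(), onset = numeric(),
                   resolution = numeric())
  disc <- data.frame(id = 1:4, arm = "comparator", time = 10 * cl, event = 0)
  cv <- curves_from_ipd(fu, resp, ae, disc, n_cycles = 5, cycle_len = cl)
  # cycle 1: nobody responded at time 0; cycle 2: 1 of 4 at risk;
  # cycle 3+: patient 4 left, responders 2 of 3
  expect_equal(cv$comparator$resp,
               c(0, 0.25, 1 / 3, 2 / 3, 2 / 3))
})

test_that("simulated prevalence matches the generating episode process", {
  # constant episode rate over a fixed on-treatment window with known
  # duration distribution: equilibrium prevalence ~ rate * mean duration
  set.seed(99)
  n <- 2000
  rate <- 1.5
  dmean <- exp(log(0.06) + 0.5^2 / 2)
  fu <- data.frame(id = 1:n, arm = "comparator", pf_exit_time = 1)
  disc <- data.frame(id = 1:n, arm = "comparator", time = 1, event = 0)
  resp <- data.frame(id = integer(), arm = character(), time = numeric())
  eps <- list()
  for (i in 1:n) {
    k <- rpois(1, rate * 1)
    if (k) {
      on <- runif(k, 0, 1)
      eps[[i]] <- data.frame(id = i, arm = "comparator",
                             category = "anemia", grade = 3, onset = on,
                             resolution = on + rlnorm(k, log(0.06), 0.5))
    }
  }
  ae <- do.call(rbind, eps)
  cv <- curves_from_ipd(fu, resp, ae, disc, n_cycles = 15, cycle_len = cl)
  mid <- cv$comparator$ae_prev[6:12, "anemia"]
  # per-cycle window widens point prevalence by ~ one cycle length
  expected <- 1 - exp(-rate * (dmean + cl))
  expect_equal(mean(mid), expected, tolerance = 0.15)
})

test_that("on-treatment curve is the Kaplan-Meier of discontinuation", {
  set.seed(12)
  n <- 500
  t_disc <- rexp(n, 1.2)
  fu_t <- rep(1.2, n)
  disc <- data.frame(id = 1:n, arm = "intervention",
                     time = pmin(t_disc, fu_t),
                     event = as.integer(t_disc < fu_t))
  fu <- data.frame(id = 1:n, arm = "intervention", pf_exit_time = fu_t)
  resp <- data.frame(id = integer(), arm = character(), time = numeric())
  ae <- data.frame(id = integer(), arm = character(), category = character(),
                   grade = integer(), onset = numeric(),
                   resolution = numeric())
  cv <- curves_from_ipd(fu, resp, ae, disc, n_cycles = 20, cycle_len = cl)
  ot <- cv$intervention$on_treat
  expect_true(all(diff(ot) <= 1e-12))
  starts <- (0:19) * cl
  expect_equal(ot, exp(-1.2 * starts), tolerance = 0.08)
})

test_that("invalid episode records are rejected", {
  fu <- data.frame(id = 1, arm = "comparator", pf_exit_time = 1)
  resp <- data.frame(id = integer(), arm = character(), time = numeric())
  disc <- data.frame(id = 1, arm = "comparator", time = 1, event = 0)
  ae <- data.frame(id = 1, arm = "comparator", category = "anemia",
                   grade = 3, onset = 0.5, resolution = 0.2)
  expect_error(curves_from_ipd(fu, resp, ae, disc, 4), "resolution")
})
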