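small_gen <- function(n = 80, ...) {
  generator_config(n = c(intervention = n, comparator = n), ...)
}

test_that("the generator is reproducible and respects the topology", {
  cfg <- small_gen(40)
  c1 <- simulate_cohort(cfg, seed = 5)
  c2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(c1$events, c3$events))

  ev <- c1$events
  topo <- state_topology()
  done <- ev[ev$event == 1, ]
  for (i in seq_len(nrow(done)))
    expect_true(done$destination[i] %in% names(topo[[done$origin[i]]]))
  # times strictly increasing within patient
  for (pid in unique(ev$id)) {
    e <- ev[ev$id == pid, ]
    expect_true(all(diff(e$entry_time) > 0) || nrow(e) == 1)
    expect_true(all(e$time_in_state > 0))
  }
})

test_that("zero death hazards generate no deaths", {
  cfg <- small_gen(40)
  for (a in c("intervention", "comparator")) {
    for (tp in c("TP3", "TP5", "TP6"))
      cfg$survival[[a]][[tp]] <- surv_model("exponential",
                                            c(rate = 1e-12))
  }
  co <- simulate_cohort(cfg, seed = 3)
  expect_false(any(co$events$destination == "death", na.rm = TRUE))
})

test_that("competing exponential exits split by their rates", {
  cfg <- generator_config(n = c(intervention = 2, comparator = 10000),
                          censor_range = c(50, 50))
  rates <- c(TP1 = 1.5, TP2 = 0.5, TP3 = 1.0)
  for (tp in names(rates))
    cfg$survival$comparator[[tp]] <-
      surv_model("exponential", c(rate = rates[[tp]]))
  co <- simulate_cohort(cfg, seed = 77, events_only = TRUE)
  pf <- co$events[co$events$origin == "PF" &
                    co$events$arm == "comparator", ]
  frac <- table(pf$destination[pf$event == 1]) / sum(pf$event == 1)
  expect_equal(unname(frac[["PD_noBM"]]), 0.5, tolerance = 0.05)
  expect_equal(unname(frac[["PD_BM"]]), 1 / 6, tolerance = 0.12)
  expect_equal(unname(frac[["death"]]), 1 / 3, tolerance = 0.07)
  # sojourn distribution is exponential with the total rate
  expect_equal(mean(pf$time_in_state), 1 / 3, tolerance = 0.05)
})

test_that("transition datasets lay out sojourns with competing censoring", {
  ev <- data.frame(
    id = c(1, 1, 2), arm = "comparator",
    origin = c("PF", "PD_noBM", "PF"),
    entry_time = c(0, 0.5, 0),
    time_in_state = c(0.5, 0.3, 0.9),
    event = c(1L, 1L, 0L),
    destination = c("PD_noBM", "death", NA))
  d <- to_transition_datasets(ev)
  row <- function(tp, id) d[d$transition_id == tp & d$id == id, ]
  expect_equal(row("TP1", 1)$time_years, 0.5)
  expect_equal(row("TP1", 1)$event, 1L)
  expect_equal(row("TP2", 1)$event, 0L)
  expect_equal(row("TP3", 1)$event, 0L)
  expect_equal(row("TP5", 1)$time_years, 0.3)
  expect_equal(row("TP5", 1)$event, 1L)
  expect_equal(row("TP4", 1)$event, 0L)
  # censored-in-PF patient: censored rows for TP1-TP3 only
  expect_equal(nrow(d[d$id == 2, ]), 3)
  expect_true(all(d$event[d$id == 2] == 0L))

  bad <- ev
  bad$destination[2] <- "PF"
  expect_error(to_transition_datasets(bad), "topology")
})

test_that("fitting the generating family to a large cohort recovers truth", {
  cfg <- generator_config(n = c(intervention = 2, comparator = 4000),
                          censor_range = c(1.8, 1.8))
  co <- simulate_cohort(cfg, seed = 31, events_only = TRUE)
  d <- to_transition_datasets(co)
  tp1 <- d[d$transition_id == "TP1" & d$arm == "comparator", ]
  f <- fit_transition(tp1, family = "weibull")
  truth <- cfg$survival$comparator$TP1$params
  expect_lt(abs(f$params["shape"] - truth["shape"]) / truth["shape"], 0.10)
  expect_lt(abs(f$params["scale"] - truth["scale"]) / truth["scale"], 0.10)
  # Gompertz truth on the death-with-BM pathway
  cfg2 <- generator_config(n = c(intervention = 2, comparator = 3000),
                           censor_range = c(3, 3))
  cfg2$survival$comparator$TP6 <- surv_model("gompertz",
                                             c(shape = 0.8, rate = 1.0))
  co2 <- simulate_cohort(cfg2, seed = 32, events_only = TRUE)
  d2 <- to_transition_datasets(co2)
  tp6 <- d2[d2$transition_id == "TP6" & d2$arm == "comparator", ]
  f6 <- fit_transition(tp6, family = "gompertz")
  expect_lt(abs(f6$params["shape"] - 0.8) / 0.8, 0.15)
  expect_lt(abs(f6$params["rate"] - 1.0) / 1.0, 0.10)
})

test_that("generated utility panel means match the truth", {
  co <- simulate_cohort(small_gen(150), seed = 9)
  pre <- co$panel[co$panel$response == 0 & co$panel$ae_leukocyte == 0 &
                    co$panel$ae_anemia == 0 & co$panel$ae_platelet == 0, ]
  se <- sd(pre$utility) / sqrt(length(unique(pre$id)))
  expect_lt(abs(mean(pre$utility) - 0.74), 3 * se)
})

test_that("cohort CSV export writes every schema", {
  co <- simulate_cohort(small_gen(15), seed = 2)
  dir <- tempfile()
  write_cohort_csv(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("transitions.csv", "panel.csv", "ae.csv", "response.csv",
           "discontinuation.csv", "followup.csv", "ground_truth.json")))))
  back <- read_transition_data(file.path(dir, "transitions.csv"))
  expect_gt(nrow(back), 0)
})
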