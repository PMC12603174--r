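# Synthetic individual-patient-data generator. Emulates the trial-like IPD
# the model consumes (multistate event histories with right censoring,
# longitudinal utility observations, adverse-event episodes, treatment
# discontinuation) with known ground truth, so fitting, GEE estimation,
# curve construction and the end-to-end cohort model are all testable
# without restricted data.

#' Generator configuration
#'
#' Defaults emulate the trial conditions: 201 / 202 patients per arm, the
#' package's synthetic base-case transition hazards as ground truth,
#' administrative censoring between 1.2 and 2.2 years (staggered accrual
#' under a median follow-up of about 1.6 years), response and
#' discontinuation dynamics matching the base-case curves, and the
#' published utility values as the utility-model truth.
#'
#' @param n Named patients per arm.
#' @param survival Per-arm, per-transition \code{\link{surv_model}} truth;
#'   default: the \code{\link{default_params}} survival set.
#' @param censor_range Administrative censoring window (years), sampled
#'   uniformly.
#' @param resp_prob,resp_onset_mean Probability of ever responding and mean
#'   response-onset time (years), per arm.
#' @param disc_rate Treatment-discontinuation hazard (per year) per arm.
#' @param max_treat_cycles Hard treatment stop per arm (induction-only for
#'   the comparator).
#' @param ae_rates On-treatment adverse-event onset rates per category
#'   (episodes per patient-year), per arm.
#' @param ae_dur_meanlog,ae_dur_sdlog Log-normal episode-duration
#'   parameters (years).
#' @param ae_grade_probs Probabilities of episode grades 2, 3, 4 (grade-2
#'   episodes exist so the grade-3+ inclusion filter has work to do).
#' @param utilities Utility-model truth (as in \code{\link{cea_params}}).
#' @param sd_patient,sd_resid Patient random-intercept and residual SDs of
#'   the utility observations.
#' @param cycle_len Cycle length in years.
#' @return List of class \code{generator_config}.
#' @export
generator_config <- function(
    n = c(intervention = 201, comparator = 202),
    survival = default_params()$survival,
    censor_range = c(1.2, 2.2),
    resp_prob = c(intervention = 0.60, comparator = 0.58),
    resp_onset_mean = 0.12,
    disc_rate = c(intervention = 0.9, comparator = 0.5),
    max_treat_cycles = c(intervention = Inf, comparator = 4),
    ae_rates = list(
      intervention = c(leukocyte = 2.4, anemia = 0.9, platelet = 0.6),
      comparator = c(leukocyte = 2.0, anemia = 0.9, platelet = 0.45)),
    ae_dur_meanlog = log(0.06), ae_dur_sdlog = 0.5,
    ae_grade_probs = c(`2` = 0.30, `3` = 0.55, `4` = 0.15),
    utilities = list(u_pf_pre = 0.74, u_pf_post = 0.81,
                     disutilities = c(leukocyte = -0.0005,
                                      anemia = -0.0124,
                                      platelet = -0.0692)),
    sd_patient = 0.05, sd_resid = 0.08,
    cycle_len = 21 / 365.25) {
  stopifnot(all(n >= 2), all(unlist(ae_rates) >= 0),
            sd_patient >= 0, sd_resid >= 0,
            censor_range[1] > 0, diff(censor_range) >= 0)
  structure(as.list(environment()), class = "generator_config")
}

# Direct closed-form H and h closures for the simulation's root solves
# (the general evaluator's dispatch is too slow inside uniroot). The
# generalized gamma falls back to the general evaluator.
.fun_closure <- function(model, prefix) {
  p <- unname(model$params)
  if (prefix == "H") {
    switch(model$family,
      exponential = function(t) p[1] * t,
      weibull = function(t) (t / p[2])^p[1],
      gompertz = if (abs(p[1]) < 1e-12) function(t) p[2] * t
                 else function(t) p[2] / p[1] * (exp(p[1] * t) - 1),
      loglogistic = function(t) log1p((t / p[2])^p[1]),
      lognormal = function(t) -pnorm(log(pmax(t, 1e-300)), p[1], p[2],
                                     lower.tail = FALSE, log.p = TRUE),
      function(t) surv_eval(model, t, "H"))
  } else {
    switch(model$family,
      exponential = function(t) p[1],
      weibull = function(t) p[1] / p[2] * (t / p[2])^(p[1] - 1),
      gompertz = function(t) p[2] * exp(p[1] * t),
      loglogistic = function(t) {
        z <- (t / p[2])^p[1]
        (p[1] / t) * z / (1 + z)
      },
      lognormal = function(t) {
        stats::dlnorm(t, p[1], p[2]) /
          stats::plnorm(t, p[1], p[2], lower.tail = FALSE)
      },
      function(t) surv_eval(model, t, "h"))
  }
}

# Per-origin-state exit evaluators for one arm.
.exit_funs <- function(models) {
  lapply(.topology, function(tps) {
    list(dests = names(tps),
         H = lapply(models[tps], .fun_closure, prefix = "H"),
         h = lapply(models[tps], .fun_closure, prefix = "h"))
  })
}

# One clock-reset multistate trajectory by total-hazard inversion: the
# sojourn solves H_tot(s) = E with E ~ Exp(1); the cause is apportioned by
# the cause-specific hazard ratio at the event time. Exact for the model
# class; a hazard plateau below the target (Gompertz, negative shape) ends
# as administrative censoring, not an error.
.sim_path <- function(exit_funs, cens) {
  state <- "PF"
  t <- 0
  origin <- character(3); entry <- numeric(3); sojourn <- numeric(3)
  event <- integer(3); destination <- character(3)
  k <- 0L
  repeat {
    ef <- exit_funs[[state]]
    Hs <- ef$H
    Htot <- if (length(Hs) == 1L) Hs[[1]] else function(x) {
      tot <- 0
      for (f in Hs) tot <- tot + f(x)
      tot
    }
    rem <- cens - t
    E <- rexp(1)
    Hrem <- Htot(rem)
    k <- k + 1L
    if (!is.finite(Hrem) || E >= Hrem) {
      origin[k] <- state; entry[k] <- t; sojourn[k] <- rem
      event[k] <- 0L; destination[k] <- NA_character_
      break
    }
    s <- uniroot(function(x) Htot(x) - E, lower = 0, upper = rem,
                 tol = 1e-9)$root
    dests <- ef$dests
    dest <- if (length(dests) == 1L) dests else {
      h <- vapply(ef$h, function(f) f(s), numeric(1))
      sample(dests, 1, prob = pmax(h, 1e-300))
    }
    origin[k] <- state; entry[k] <- t; sojourn[k] <- s
    event[k] <- 1L; destination[k] <- dest
    t <- t + s
    if (dest == "death") break
    state <- dest
  }
  list(origin = origin[1:k], entry_time = entry[1:k],
       time_in_state = sojourn[1:k], event = event[1:k],
       destination = destination[1:k], n = k)
}

#' Generate a synthetic cohort
#'
#' @param config A \code{\link{generator_config}}.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param events_only Skip the utility panel / adverse-event / response /
#'   discontinuation records (faster; used by large occupancy checks).
#' @return Object of class \code{synthetic_cohort}: \code{events}
#'   (multistate visit records), \code{followup}, \code{response},
#'   \code{ae}, \code{discontinuation}, \code{panel} and the
#'   \code{ground_truth} configuration.
#' @export
simulate_cohort <- function(config, seed = 1, events_only = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  cl <- config$cycle_len
  events <- list(); resp <- list(); aes <- list()
  disc <- list(); panel <- list()
  n_total <- sum(unlist(config$n))
  fu_id <- integer(n_total); fu_arm <- character(n_total)
  fu_exit <- numeric(n_total)
  pid <- 0L
  for (arm in names(config$n)) {
    exit_funs <- .exit_funs(config$survival[[arm]])
    for (i in seq_len(config$n[[arm]])) {
      pid <- pid + 1L
      cens <- runif(1, config$censor_range[1], config$censor_range[2])
      path <- .sim_path(exit_funs, cens)
      path$id <- rep(pid, path$n)
      path$arm <- rep(arm, path$n)
      events[[pid]] <- path

      pf_exit <- path$time_in_state[1]
      fu_id[pid] <- pid; fu_arm[pid] <- arm; fu_exit[pid] <- pf_exit
      if (events_only) next

      # response onset (absolute time; responders only)
      resp_t <- if (runif(1) < config$resp_prob[[arm]])
        rexp(1, 1 / config$resp_onset_mean) else Inf
      if (is.finite(resp_t))
        resp[[length(resp) + 1]] <- list(id = pid, arm = arm,
                                         time = resp_t)

      # treatment discontinuation, censored by leaving PF / follow-up
      d_lat <- min(rexp(1, config$disc_rate[[arm]]),
                   config$max_treat_cycles[[arm]] * cl)
      disc[[length(disc) + 1]] <- list(
        id = pid, arm = arm,
        time = min(d_lat, pf_exit),
        event = as.integer(d_lat < pf_exit))
      on_treat_end <- min(d_lat, pf_exit)

      # adverse-event episodes: Poisson onsets while on treatment,
      # log-normal durations, categorical grades
      pat_aes <- list()
      for (cat in .ae_categories) {
        k <- rpois(1, config$ae_rates[[arm]][[cat]] * on_treat_end)
        if (k > 0) {
          onset <- sort(runif(k, 0, on_treat_end))
          dur <- rlnorm(k, config$ae_dur_meanlog, config$ae_dur_sdlog)
          grade <- as.integer(sample(names(config$ae_grade_probs), k,
                                     replace = TRUE,
                                     prob = config$ae_grade_probs))
          pat_aes[[length(pat_aes) + 1]] <- data.frame(
            id = pid, arm = arm, category = cat, grade = grade,
            onset = onset, resolution = onset + dur)
        }
      }
      if (length(pat_aes)) aes[[length(aes) + 1]] <- do.call(rbind, pat_aes)

      # utility panel: one record per PF cycle
      n_cyc <- ceiling(pf_exit / cl)
      if (n_cyc >= 1) {
        starts <- (seq_len(n_cyc) - 1) * cl
        ut <- config$utilities
        b_i <- rnorm(1, 0, config$sd_patient)
        responded <- as.integer(starts >= resp_t)
        ae_ind <- matrix(0L, n_cyc, length(.ae_categories),
                         dimnames = list(NULL, .ae_categories))
        for (a in pat_aes) {
          qual <- a$grade >= 3
          if (!any(qual)) next
          for (j in which(qual)) {
            act <- starts >= a$onset[j] & starts < a$resolution[j]
            ae_ind[act, a$category[1]] <- 1L
          }
        }
        u <- ut$u_pf_pre + (ut$u_pf_post - ut$u_pf_pre) * responded +
          drop(ae_ind %*% ut$disutilities[.ae_categories]) + b_i +
          rnorm(n_cyc, 0, config$sd_resid)
        panel[[pid]] <- data.frame(
          id = pid, arm = arm, cycle = seq_len(n_cyc),
          utility = pmin(pmax(u, -0.594), 1),
          response = responded,
          ae_leukocyte = ae_ind[, "leukocyte"],
          ae_anemia = ae_ind[, "anemia"],
          ae_platelet = ae_ind[, "platelet"])
      }
    }
  }
  pull <- function(x, f) unlist(lapply(x, `[[`, f), use.names = FALSE)
  ev <- data.frame(id = pull(events, "id"), arm = pull(events, "arm"),
                   origin = pull(events, "origin"),
                   entry_time = pull(events, "entry_time"),
                   time_in_state = pull(events, "time_in_state"),
                   event = pull(events, "event"),
                   destination = pull(events, "destination"))
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  small <- function(x) {
    if (!length(x)) return(NULL)
    as.data.frame(lapply(setNames(names(x[[1]]), names(x[[1]])),
                         function(f) pull(x, f)))
  }
  structure(list(events = ev,
                 followup = data.frame(id = fu_id[seq_len(pid)],
                                       arm = fu_arm[seq_len(pid)],
                                       pf_exit_time = fu_exit[seq_len(pid)]),
                 response = small(resp), ae = bind(aes),
                 discontinuation = small(disc), panel = bind(panel),
                 ground_truth = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d state visits\n",
              nrow(x$followup), nrow(x$events)))
  if (!is.null(x$panel))
    cat(sprintf("  %d utility records, %d AE episodes\n",
                nrow(x$panel), if (is.null(x$ae)) 0L else nrow(x$ae)))
  invisible(x)
}

#' Clock-reset transition datasets from a synthetic cohort
#'
#' Lays the multistate visit records out as one right-censored
#' time-to-event dataset per transition pathway: each visit to an origin
#' state contributes its sojourn time to every exit of that state, with the
#' event indicator set on the exit actually taken and the competing exits
#' censored at the sojourn time.
#'
#' @param cohort A \code{\link{simulate_cohort}} result, or any data.frame
#'   shaped like its \code{events} component.
#' @return data.frame \code{(id, arm, transition_id, time_years, event)}.
#' @export
to_transition_datasets <- function(cohort) {
  ev <- if (inherits(cohort, "synthetic_cohort")) cohort$events else cohort
  bad <- ev$event == 1 &
    !mapply(function(o, d) d %in% names(.topology[[o]]),
            ev$origin, ev$destination)
  if (any(bad))
    stop("event history violates the model topology", call. = FALSE)
  out <- list()
  for (origin in names(.topology)) {
    tps <- .topology[[origin]]
    sub <- ev[ev$origin == origin, , drop = FALSE]
    if (!nrow(sub)) next
    for (dest in names(tps)) {
      out[[length(out) + 1]] <- data.frame(
        id = sub$id, arm = sub$arm, transition_id = tps[[dest]],
        time_years = sub$time_in_state,
        event = as.integer(sub$event == 1 & sub$destination == dest))
    }
  }
  d <- do.call(rbind, out)
  d <- d[d$time_years > 0, ]
  rownames(d) <- NULL
  validate_transition_data(d)
}

#' Empirical state occupancy of a simulated cohort
#'
#' Proportion of patients in each state at given times. Meaningful only up
#' to the administrative censoring time: the generator's censoring window
#' should start at or beyond \code{max(times)} when this is used as an
#' occupancy oracle.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param times Evaluation times in years.
#' @param arm Arm to evaluate.
#' @return Matrix \code{length(times)} by four states.
#' @export
empirical_occupancy <- function(cohort, times,
                                arm = c("intervention", "comparator")) {
  arm <- match.arg(arm)
  ev <- cohort$events[cohort$events$arm == arm, ]
  n <- length(unique(ev$id))
  exit_t <- ev$entry_time + ev$time_in_state
  died <- ev$event == 1 & ev$destination == "death"
  occ <- matrix(0, length(times), 4, dimnames = list(NULL, .states))
  for (k in seq_along(times)) {
    t <- times[k]
    inside <- ev$entry_time <= t & t < exit_t
    occ[k, "PF"] <- sum(inside & ev$origin == "PF")
    occ[k, "PD_noBM"] <- sum(inside & ev$origin == "PD_noBM")
    occ[k, "PD_BM"] <- sum(inside & ev$origin == "PD_BM")
    occ[k, "death"] <- sum(died & exit_t <= t)
  }
  occ / n
}

#' Export a synthetic cohort to its CSV schemas
#'
#' Writes the transition dataset, utility panel, adverse-event episodes and
#' discontinuation records as CSV, and the ground-truth configuration as
#' JSON.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory (created if missing).
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(to_transition_datasets(cohort),
                   file.path(dir, "transitions.csv"), row.names = FALSE)
  for (nm in c("panel", "ae", "response", "discontinuation", "followup"))
    if (!is.null(cohort[[nm]]))
      utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  gt <- cohort$ground_truth
  gt$survival <- lapply(gt$survival, function(arm_models)
    lapply(arm_models, function(m)
      list(family = m$family, parameters = as.list(m$params))))
  jsonlite::write_json(gt[setdiff(names(gt), "cycle_len")],
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
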