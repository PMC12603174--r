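# Time-varying per-cycle curves: response proportion, adverse-event
# prevalence per category, and on-treatment proportion, either constructed
# from individual-patient event records or materialized from a parametric
# description (the package's fixture form).

.ae_categories <- c("leukocyte", "anemia", "platelet")

#' Build per-cycle curves from individual-patient event records
#'
#' Constructs, per arm and cycle: the proportion of at-risk
#' (still-in-follow-up, progression-free) patients past their treatment
#' response onset; the prevalence of active adverse-event episodes per
#' category (grade-filtered, applying the "grade 3+, incidence above 2 percent"
#' inclusion rule); and the on-treatment proportion from a product-limit
#' (Kaplan-Meier) estimate of time to treatment discontinuation with
#' administrative censoring.
#'
#' @param followup data.frame \code{(id, arm, pf_exit_time)}: end of
#'   progression-free observation in years (progression, death or censoring).
#' @param response data.frame \code{(id, arm, time)} of response-onset times
#'   (responders only).
#' @param ae data.frame \code{(id, arm, category, grade, onset, resolution)}
#'   of adverse-event episodes; overlapping episodes of one patient-category
#'   are counted once per cycle.
#' @param discontinuation data.frame \code{(id, arm, time, event)}: time to
#'   treatment discontinuation, \code{event = 0} for administrative
#'   censoring.
#' @param n_cycles Number of cycles to cover.
#' @param cycle_len Cycle length in years.
#' @param min_grade,min_incidence Adverse-event inclusion rule: episodes
#'   below \code{min_grade} are ignored; categories whose patient-level
#'   incidence is at most \code{min_incidence} are zeroed out.
#' @param on_treat_tail Beyond the last observed discontinuation-risk time:
#'   \code{"zero"} (default) sets the on-treatment proportion to 0,
#'   \code{"carry"} holds the last estimate. Response and prevalence curves
#'   always carry their last at-risk value.
#' @return Object of class \code{tv_curves}: per arm, a list with vectors
#'   \code{resp}, \code{on_treat} and matrix \code{ae_prev}
#'   (\code{n_cycles} by category).
#' @export
curves_from_ipd <- function(followup, response, ae, discontinuation,
                            n_cycles, cycle_len = 21 / 365.25,
                            min_grade = 3, min_incidence = 0.02,
                            on_treat_tail = c("zero", "carry")) {
  on_treat_tail <- match.arg(on_treat_tail)
  stopifnot(n_cycles >= 1, cycle_len > 0)
  if (nrow(ae) && any(ae$resolution < ae$onset))
    stop("adverse-event resolution precedes onset", call. = FALSE)
  if (nrow(ae) && any(ae$onset < 0))
    stop("adverse-event onset times must be non-negative", call. = FALSE)
  starts <- (seq_len(n_cycles) - 1) * cycle_len
  ends <- starts + cycle_len
  arms <- sort(unique(followup$arm))

  out <- lapply(arms, function(a) {
    fu <- followup[followup$arm == a, ]
    n_arm <- nrow(fu)
    resp_t <- response$time[response$arm == a][
      match(fu$id, response$id[response$arm == a])]
    # at-risk: still under progression-free observation at cycle start
    at_risk <- outer(fu$pf_exit_time, starts, `>`)      # n_arm x n_cycles
    n_risk <- colSums(at_risk)
    responded <- outer(ifelse(is.na(resp_t), Inf, resp_t), starts, `<=`)
    resp <- colSums(at_risk & responded) / pmax(n_risk, 1)

    aa <- ae[ae$arm == a & ae$grade >= min_grade, , drop = FALSE]
    prev <- matrix(0, n_cycles, length(.ae_categories),
                   dimnames = list(NULL, .ae_categories))
    for (cat in .ae_categories) {
      ac <- aa[aa$category == cat, , drop = FALSE]
      incidence <- length(unique(ac$id)) / max(n_arm, 1)
      if (!nrow(ac) || incidence <= min_incidence) next
      for (cyc in seq_len(n_cycles)) {
        if (n_risk[cyc] == 0) next
        active <- ac$onset < ends[cyc] & ac$resolution > starts[cyc]
        ids <- unique(ac$id[active])
        ids <- ids[ids %in% fu$id[at_risk[, cyc]]]
        prev[cyc, cat] <- length(ids) / n_risk[cyc]
      }
    }

    # carry last at-risk value into the unobserved tail
    if (any(n_risk == 0) && any(n_risk > 0)) {
      last <- max(which(n_risk > 0))
      if (last < n_cycles) {
        resp[(last + 1):n_cycles] <- resp[last]
        prev[(last + 1):n_cycles, ] <-
          matrix(prev[last, ], n_cycles - last, ncol(prev), byrow = TRUE)
      }
    }

    dd <- discontinuation[discontinuation$arm == a, ]
    if (!nrow(dd)) {
      on_treat <- rep(1, n_cycles)
    } else {
      km <- survival::survfit(survival::Surv(time, event) ~ 1, data = dd)
      on_treat <- summary(km, times = starts, extend = TRUE)$surv
      beyond <- starts > max(dd$time)
      if (any(beyond))
        on_treat[beyond] <- if (on_treat_tail == "zero") 0
                            else on_treat[max(which(!beyond))]
    }
    list(resp = resp, ae_prev = prev, on_treat = on_treat)
  })
  names(out) <- arms
  structure(out, n_cycles = n_cycles, cycle_len = cycle_len,
            class = "tv_curves")
}

# Materialize parametric fixture curves for one arm over n cycles.
# resp(c)      = resp_max (1 - exp(-(c-1)/resp_tau))
# ae_prev(c,k) = ae_peak_k exp(-(c-1)/ae_tau)
# on_treat(c)  = exp(-disc_rate (c-1) cycle_len), truncated at max_cycles
.materialize_curves <- function(cp, n_cycles, cycle_len) {
  cyc0 <- seq_len(n_cycles) - 1
  resp <- cp$resp_max * (1 - exp(-cyc0 / cp$resp_tau))
  prev <- vapply(.ae_categories,
                 function(k) cp$ae_peak[[k]] * exp(-cyc0 / cp$ae_tau),
                 numeric(n_cycles))
  prev <- matrix(prev, n_cycles, dimnames = list(NULL, .ae_categories))
  on_treat <- exp(-cp$disc_rate * cyc0 * cycle_len)
  if (is.finite(cp$max_treat_cycles))
    on_treat[cyc0 + 1 > cp$max_treat_cycles] <- 0
  list(resp = resp, ae_prev = prev, on_treat = on_treat)
}

# Curves for one arm at the model's horizon, whatever their representation.
.arm_curves <- function(params, arm, n_cycles, cycle_len) {
  cv <- params$curves[[arm]]
  if (is.null(cv)) stop("no curves for arm '", arm, "'", call. = FALSE)
  if (!is.null(cv$resp_max))
    return(.materialize_curves(cv, n_cycles, cycle_len))
  # materialized curves: recycle the last value over a longer horizon
  ext <- function(x, n) {
    if (length(x) >= n) x[seq_len(n)] else c(x, rep(x[length(x)], n - length(x)))
  }
  prev <- cv$ae_prev
  if (nrow(prev) < n_cycles)
    prev <- rbind(prev, matrix(prev[nrow(prev), ], n_cycles - nrow(prev),
                               ncol(prev), byrow = TRUE))
  ot <- ext(cv$on_treat, n_cycles)
  list(resp = ext(cv$resp, n_cycles), ae_prev = prev[seq_len(n_cycles), ,
                                                     drop = FALSE],
       on_treat = ot)
}

#' Export per-cycle curves to CSV
#'
#' @param curves A \code{tv_curves} object (or the parametric fixture form
#'   materialized at \code{n_cycles}).
#' @param path Output path.
#' @export
write_curves_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(a) {
    cv <- curves[[a]]
    n <- length(cv$resp)
    data.frame(arm = a, cycle = seq_len(n), resp = cv$resp,
               on_treat = cv$on_treat, cv$ae_prev)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
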