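# Transition engine: competing cause-specific hazards -> per-cycle transition
# probabilities under clock-reset (time-since-state-entry) semantics.
#
# Model topology (four states):
#   PF       -> PD_noBM (TP1), PD_BM (TP2), death (TP3)
#   PD_noBM  -> PD_BM (TP4), death (TP5)
#   PD_BM    -> death (TP6)
#   death    absorbing

.states <- c("PF", "PD_noBM", "PD_BM", "death")

.topology <- list(
  PF      = c(PD_noBM = "TP1", PD_BM = "TP2", death = "TP3"),
  PD_noBM = c(PD_BM = "TP4", death = "TP5"),
  PD_BM   = c(death = "TP6")
)

#' Model state topology
#'
#' @return Named list mapping each transient origin state to its exit
#'   destinations and transition labels (TP1--TP6).
#' @export
state_topology <- function() .topology

#' Per-cycle competing-exit probabilities under clock reset
#'
#' For a state entered \code{d} completed cycles ago, computes the probability
#' of each competing exit during the next cycle. Cause-specific hazards are
#' treated as piecewise-constant within the cycle: with
#' \eqn{u = d \cdot \Delta}, \eqn{\Delta H_k = H_k(u+\Delta) - H_k(u)} and
#' \eqn{\Delta H = \sum_k \Delta H_k}, the total exit probability is
#' \eqn{1 - e^{-\Delta H}} apportioned as
#' \eqn{p_k = (\Delta H_k / \Delta H)(1 - e^{-\Delta H})}. This is exact for
#' exponential hazards and consistent as the cycle length shrinks; the stay
#' probability \eqn{e^{-\Delta H}} is exact for any family because
#' \eqn{e^{-\Delta H} = S(u+\Delta)/S(u)} of the sojourn distribution.
#'
#' @param exits List of \code{surv_model} objects, one per competing exit.
#' @param d Duration index (completed cycles since state entry), scalar or
#'   vector.
#' @param cycle_len Cycle length in years.
#' @return If \code{d} is scalar, a named vector of exit probabilities plus
#'   \code{stay}; if vector, a matrix with one row per duration.
#' @export
cycle_probabilities <- function(exits, d, cycle_len) {
  stopifnot(length(exits) >= 1, cycle_len > 0, all(d >= 0))
  u <- d * cycle_len
  dH <- vapply(exits, function(m) {
    h <- surv_eval(m, u + cycle_len, "H") - surv_eval(m, u, "H")
    pmax(h, 0)
  }, numeric(length(u)))
  dH <- matrix(dH, nrow = length(u))
  if (any(!is.finite(dH))) {
    bad <- which(!is.finite(dH), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-finite cumulative-hazard increment for exit %d near t = %.3f y (extrapolation overflow)",
      bad[2], u[bad[1]]), call. = FALSE)
  }
  tot <- rowSums(dH)
  p_exit <- -expm1(-tot)
  frac <- dH / ifelse(tot > 0, tot, 1)
  p <- frac * p_exit
  p[tot == 0, ] <- 0
  colnames(p) <- vapply(seq_along(exits), function(i) {
    nm <- names(exits)[i]
    if (is.null(nm) || !nzchar(nm)) paste0("exit", i) else nm
  }, character(1))
  out <- cbind(p, stay = exp(-tot))
  if (length(d) == 1L) out[1, ] else out
}

#' Build the full per-cycle transition schedule for one arm
#'
#' Evaluates \code{\link{cycle_probabilities}} for every transient origin
#' state over duration indices \code{0..horizon_cycles-1}.
#'
#' @param models Named list of \code{surv_model} objects, one per transition
#'   \code{TP1..TP6} (TP1: PF to PD without brain metastases; TP2: PF to PD
#'   with brain metastases; TP3: PF to death; TP4: PD without to PD with
#'   brain metastases; TP5: PD without brain metastases to death; TP6: PD
#'   with brain metastases to death).
#' @param horizon_cycles Number of cycles.
#' @param cycle_len Cycle length in years.
#' @return Object of class \code{cycle_schedule}: a list with one probability
#'   matrix per origin state (rows = duration index starting at 0, columns =
#'   destinations plus \code{stay}) and attributes \code{cycle_len},
#'   \code{horizon_cycles}.
#' @export
build_schedule <- function(models, horizon_cycles, cycle_len) {
  stopifnot(horizon_cycles >= 1)
  missing <- setdiff(unlist(.topology), names(models))
  if (length(missing))
    stop("missing transition model(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- seq_len(horizon_cycles) - 1
  sched <- lapply(names(.topology), function(origin) {
    tps <- .topology[[origin]]
    exits <- setNames(models[tps], names(tps))
    cycle_probabilities(exits, d, cycle_len)
  })
  names(sched) <- names(.topology)
  structure(sched, cycle_len = cycle_len, horizon_cycles = horizon_cycles,
            class = "cycle_schedule")
}

#' Export a transition schedule to long-format CSV
#'
#' @param schedule A \code{cycle_schedule}.
#' @param path Output CSV path.
#' @param arm Optional arm label column.
#' @export
write_schedule_csv <- function(schedule, path, arm = NA_character_) {
  rows <- do.call(rbind, lapply(names(schedule), function(origin) {
    m <- schedule[[origin]]
    data.frame(arm = arm, origin = origin,
               duration_index = rep(seq_len(nrow(m)) - 1, ncol(m)),
               destination = rep(colnames(m), each = nrow(m)),
               probability = as.vector(m))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
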