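# Cost-effectiveness summary measures.

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (intervention minus comparator), NT$.
#' @param delta_effect Incremental effect (QALYs or LYs).
#' @return A list with \code{value} (the ratio, or \code{NA} when dominance
#'   applies or the effect difference is zero) and \code{label}: one of
#'   \code{"ratio"}, \code{"dominant"} (cheaper and more effective),
#'   \code{"dominated"} (costlier and less effective) or \code{"undefined"}
#'   (zero effect difference).
#' @examples
#' icer(2111359, 0.721)  # NT$2,928,376 per QALY at display rounding
#' @export
icer <- function(delta_cost, delta_effect) {
  stopifnot(is.finite(delta_cost), is.finite(delta_effect))
  if (delta_effect == 0)
    return(list(value = NA_real_, label = "undefined"))
  if (delta_cost < 0 && delta_effect > 0)
    return(list(value = NA_real_, label = "dominant"))
  if (delta_cost > 0 && delta_effect < 0)
    return(list(value = NA_real_, label = "dominated"))
  list(value = delta_cost / delta_effect, label = "ratio")
}

#' Incremental net monetary benefit
#'
#' \eqn{INMB = \lambda \Delta E - \Delta C} at willingness-to-pay
#' \eqn{\lambda}; positive values indicate the intervention is cost-effective
#' at that threshold.
#'
#' @param delta_cost,delta_effect Incremental cost and effect.
#' @param wtp Willingness-to-pay per effect unit.
#' @export
inmb <- function(delta_cost, delta_effect, wtp) {
  stopifnot(wtp >= 0)
  wtp * delta_effect - delta_cost
}

#' Cost-effectiveness plane quadrant
#'
#' @param delta_cost,delta_effect Incremental cost and effect.
#' @return \code{"NE"}, \code{"NW"}, \code{"SE"} or \code{"SW"} (effect on
#'   the x axis, cost on the y axis; boundary values classified with the
#'   non-negative side).
#' @export
ce_quadrant <- function(delta_cost, delta_effect) {
  ew <- ifelse(delta_effect >= 0, "E", "W")
  ns <- ifelse(delta_cost >= 0, "N", "S")
  paste0(ns, ew)
}

# Display rounding used in printed summaries: integer NT$ (banker's
# rounding), effects to 3 decimals.
.fmt_money <- function(x) formatC(round(x, 0), format = "d", big.mark = ",")
.fmt_eff <- function(x) formatC(round(x, 3), format = "f", digits = 3)

#' Summarize incremental results
#'
#' @param delta_cost,delta_qaly,delta_ly Incremental outcomes.
#' @param wtp Willingness-to-pay per QALY (also applied per LY for the
#'   LY-based summary).
#' @return Object of class \code{cea_summary} holding ICER and INMB per QALY
#'   and per LY, and the plane quadrant.
#' @export
cea_summary <- function(delta_cost, delta_qaly, delta_ly = NA_real_,
                        wtp = 3023055) {
  structure(list(
    delta_cost = delta_cost, delta_qaly = delta_qaly, delta_ly = delta_ly,
    wtp = wtp,
    icer_qaly = icer(delta_cost, delta_qaly),
    inmb_qaly = inmb(delta_cost, delta_qaly, wtp),
    icer_ly = if (is.na(delta_ly)) NULL else icer(delta_cost, delta_ly),
    inmb_ly = if (is.na(delta_ly)) NA_real_
              else inmb(delta_cost, delta_ly, wtp),
    quadrant = ce_quadrant(delta_cost, delta_qaly)), class = "cea_summary")
}

#' @export
print.cea_summary <- function(x, ...) {
  cat("Incremental cost-effectiveness summary (NT$)\n")
  cat(sprintf("  ΔCost  %s\n", .fmt_money(x$delta_cost)))
  cat(sprintf("  ΔQALY  %s   ΔLY  %s\n", .fmt_eff(x$delta_qaly),
              if (is.na(x$delta_ly)) "-" else .fmt_eff(x$delta_ly)))
  ic <- x$icer_qaly
  cat(sprintf("  ICER   %s per QALY\n",
              if (ic$label == "ratio") .fmt_money(ic$value) else ic$label))
  if (!is.null(x$icer_ly)) {
    il <- x$icer_ly
    cat(sprintf("  ICER   %s per LY\n",
                if (il$label == "ratio") .fmt_money(il$value) else il$label))
  }
  cat(sprintf("  INMB   %s per QALY (WTP %s)\n", .fmt_money(x$inmb_qaly),
              .fmt_money(x$wtp)))
  if (!is.na(x$inmb_ly))
    cat(sprintf("  INMB   %s per LY\n", .fmt_money(x$inmb_ly)))
  cat(sprintf("  quadrant %s\n", x$quadrant))
  invisible(x)
}
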