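# Base-graphics displays: cost-effectiveness plane, acceptability curve,
# tornado diagram, and a visual fit report for survival model selection.

#' @export
plot.cea_psa <- function(x, which = c("plane", "ceac"), ...) {
  which <- match.arg(which)
  d <- x$draws
  if (which == "plane") {
    graphics::plot(d$delta_qaly, d$delta_cost, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.3),
                   xlab = "incremental QALYs",
                   ylab = "incremental cost (NT$)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey60")
    graphics::abline(0, x$wtp, lty = 2)
  } else {
    cc <- ceac(x)
    graphics::plot(cc$wtp, cc$p_ce, type = "l", ylim = c(0, 1),
                   xlab = "willingness-to-pay per QALY (NT$)",
                   ylab = "P(cost-effective)",
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(v = x$wtp, lty = 2)
  }
  invisible(x)
}

#' @export
plot.cea_dsa <- function(x, n = 12, ...) {
  tab <- utils::head(x$table, n)
  tab <- tab[nrow(tab):1, ]
  lo <- pmin(tab$inmb_low, tab$inmb_high)
  hi <- pmax(tab$inmb_low, tab$inmb_high)
  old <- graphics::par(mar = c(5, 16, 3, 2))
  on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = range(c(lo, hi, x$base_inmb)),
                 ylim = c(0.5, nrow(tab) + 0.5), yaxt = "n",
                 xlab = "INMB (NT$)", ylab = "",
                 main = "Tornado diagram (one-way DSA)", ...)
  graphics::abline(v = x$base_inmb, lty = 2)
  graphics::rect(lo, seq_len(nrow(tab)) - 0.35, hi,
                 seq_len(nrow(tab)) + 0.35, col = "lightsteelblue")
  graphics::axis(2, at = seq_len(nrow(tab)), labels = tab$parameter,
                 las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Visual fit report for candidate survival families
#'
#' Overlays the Kaplan-Meier estimate of one transition dataset with the
#' fitted parametric survival curves, the plotting companion to AIC/BIC
#' ranking.
#'
#' @param time,event The transition dataset (as in
#'   \code{\link{fit_transition}}).
#' @param fits List of fitted \code{surv_model}s.
#' @param t_max Extrapolation limit for display, years.
#' @param ... Passed to \code{plot}.
#' @export
plot_fit_report <- function(time, event, fits, t_max = NULL, ...) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time_years
  }
  km <- survival::survfit(survival::Surv(time, event) ~ 1)
  if (is.null(t_max)) t_max <- 2 * max(time)
  graphics::plot(km, conf.int = FALSE, xlim = c(0, t_max),
                 xlab = "years since state entry", ylab = "S(t)",
                 main = "Parametric fits vs Kaplan-Meier", ...)
  tt <- seq(0, t_max, length.out = 200)
  for (i in seq_along(fits))
    graphics::lines(tt, surv_eval(fits[[i]], tt, "S"), col = i + 1)
  graphics::legend("topright",
                   legend = vapply(fits, `[[`, character(1), "family"),
                   col = seq_along(fits) + 1, lty = 1, cex = 0.8)
  invisible(fits)
}
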