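#' Read clock-reset transition datasets from CSV
#'
#' Expects columns \code{id, arm, transition_id, time_years, event}. Times are
#' sojourn times measured from entry into the origin state (clock-reset
#' layout); \code{event} is 1 if the transition occurred and 0 if the sojourn
#' was censored (by a competing exit or administratively).
#'
#' @param path CSV file path.
#' @return A data.frame validated against the schema.
#' @export
read_transition_data <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_transition_data(d)
}

#' Validate a transition dataset
#'
#' @param d data.frame with columns \code{id, arm, transition_id, time_years,
#'   event}.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_transition_data <- function(d) {
  needed <- c("id", "arm", "transition_id", "time_years", "event")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop("transition data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(d$time_years)) || any(d$time_years <= 0))
    stop("time_years must be finite and strictly positive", call. = FALSE)
  if (!all(d$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (transition)", call. = FALSE)
  d
}

#' Fit one parametric family to single-transition time-to-event data
#'
#' Maximum-likelihood fit of one of the six standard families to right-censored
#' sojourn times for a single transition pathway, maximizing
#' \eqn{\sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)}. Fitting is
#' delegated to \code{flexsurv::flexsurvreg}; the returned object carries the
#' coefficients on the unconstrained scale, the observed-information
#' covariance, the log-likelihood and AIC/BIC.
#'
#' @param time Positive sojourn times in years, or a data.frame with columns
#'   \code{time_years} and \code{event} (as from
#'   \code{\link{read_transition_data}}, already filtered to one transition
#'   and arm).
#' @param event 0/1 event indicators (ignored when \code{time} is a
#'   data.frame).
#' @param family One of \code{surv_families()}.
#' @param transition,arm Optional labels stored on the fit.
#' @return An object of classes \code{surv_fit} and \code{surv_model}.
#' @examples
#' set.seed(1)
#' t <- rweibull(200, 1.3, 0.8)
#' f <- fit_transition(pmin(t, 2), as.numeric(t < 2), "weibull")
#' coef(f); AIC(f)
#' @export
fit_transition <- function(time, event = NULL,
                           family = surv_families(),
                           transition = NA_character_,
                           arm = NA_character_) {
  family <- match.arg(family)
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time_years
  }
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and strictly positive", call. = FALSE)
  if (is.null(event) || length(event) != length(time) ||
      !all(event %in% c(0, 1)))
    stop("event must be a 0/1 vector matching time", call. = FALSE)
  info <- .family_info(family)
  n_ev <- sum(event)
  if (n_ev < info$n_params)
    stop(sprintf(
      "degenerate fit: %d event(s) but family '%s' has %d parameter(s)",
      n_ev, family, info$n_params), call. = FALSE)

  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, dist = info$dist),
    error = function(e) e, warning = function(w) {
      # retry quietly; flexsurv warns on non-invertible Hessians
      suppressWarnings(
        flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                              dist = info$dist))
    })
  if (inherits(fit, "error"))
    stop(sprintf("fit of family '%s' failed to converge: %s",
                 family, conditionMessage(fit)), call. = FALSE)

  natural <- fit$res[info$pars, "est"]
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  if (!is.null(vc)) {
    vc <- (vc + t(vc)) / 2
    if (any(!is.finite(vc))) vc <- NULL
  }
  m <- surv_model(family, natural, vcov = vc, loglik = fit$loglik,
                  n_events = as.integer(n_ev), n_obs = length(time),
                  transition = transition, arm = arm)
  m$AIC <- 2 * info$n_params - 2 * fit$loglik
  m$BIC <- info$n_params * log(length(time)) - 2 * fit$loglik
  class(m) <- c("surv_fit", class(m))
  m
}

#' @export
AIC.surv_model <- function(object, ..., k = 2) {
  k * length(object$params) - 2 * object$loglik
}

#' @export
BIC.surv_model <- function(object, ...) {
  length(object$params) * log(object$n_obs) - 2 * object$loglik
}

#' @export
predict.surv_model <- function(object, t,
                               type = c("survival", "hazard", "cumhaz",
                                        "density"), ...) {
  type <- match.arg(type)
  surv_eval(object, t, switch(type, survival = "S", hazard = "h",
                              cumhaz = "H", density = "f"))
}

#' @export
plot.surv_model <- function(x, t_max = 5, n = 200, what = "survival", ...) {
  t <- seq(0, t_max, length.out = n)
  y <- predict(x, t, type = what)
  graphics::plot(t, y, type = "l", xlab = "years since state entry",
                 ylab = what,
                 main = sprintf("%s (%s, %s)", x$family,
                                x$transition, x$arm), ...)
  invisible(x)
}

#' Fit all six families to one transition dataset
#'
#' @inheritParams fit_transition
#' @param families Families to attempt; defaults to all six. Families whose
#'   fit fails (e.g. too few events for a three-parameter family) are dropped
#'   with a message.
#' @return List of \code{surv_fit} objects.
#' @export
fit_all_families <- function(time, event = NULL, families = surv_families(),
                             transition = NA_character_,
                             arm = NA_character_) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(
      fit_transition(time, event, fam, transition = transition, arm = arm),
      error = function(e) {
        message(sprintf("family '%s' skipped: %s", fam, conditionMessage(e)))
        NULL
      })
    if (!is.null(f)) fits[[fam]] <- f
  }
  fits
}

#' Rank candidate fits for one transition by information criteria
#'
#' Computes AIC \eqn{= 2k - 2\ell} and BIC \eqn{= k\log n - 2\ell} for each
#' fit and ranks by AIC, breaking exact ties by fewer parameters and then by
#' the fixed family order. The returned table flags the best fit (base case),
#' the second-best (alternative-fit scenario) and the lowest-three candidate
#' set used by the optimistic/pessimistic scenarios.
#'
#' @param fits Non-empty list of \code{surv_fit}/\code{surv_model} objects
#'   fitted to the same dataset.
#' @return A list with \code{table} (data.frame with family, k, loglik, AIC,
#'   BIC, rank) and \code{fits} (the input fits in ranked order).
#' @export
select_models <- function(fits) {
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  n_obs <- unique(vapply(fits, function(f) f$n_obs, integer(1)))
  if (length(n_obs) != 1)
    stop("fits were not produced from the same dataset", call. = FALSE)
  fam <- vapply(fits, function(f) f$family, character(1))
  k <- vapply(fits, function(f) length(f$params), numeric(1))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  aic <- 2 * k - 2 * ll
  bic <- k * log(n_obs) - 2 * ll
  ord <- order(aic, k, match(fam, surv_families()))
  tab <- data.frame(family = fam[ord], k = k[ord], loglik = ll[ord],
                    AIC = aic[ord], BIC = bic[ord], rank = seq_along(ord),
                    row.names = NULL)
  list(table = tab, fits = fits[ord])
}

#' Write fitted transition models to JSON
#'
#' @param models Named list (or list of lists) of \code{surv_model} objects.
#' @param path Output path.
#' @export
write_models_json <- function(models, path) {
  ser <- function(m) {
    if (inherits(m, "surv_model")) {
      list(family = m$family,
           parameter_names = names(m$params),
           parameters = unname(m$params),
           coefficients = unname(m$coefficients),
           vcov = if (is.null(m$vcov)) NULL else unclass(m$vcov),
           loglik = m$loglik, n_events = m$n_events, n_obs = m$n_obs,
           AIC = AIC(m), BIC = BIC(m),
           transition = m$transition, arm = m$arm)
    } else lapply(m, ser)
  }
  jsonlite::write_json(ser(models), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read fitted transition models from JSON
#'
#' @param path Path written by \code{\link{write_models_json}}.
#' @return Nested list of \code{surv_model} objects.
#' @export
read_models_json <- function(path) {
  de <- function(x) {
    if (is.list(x) && !is.null(x$family)) {
      p <- setNames(unlist(x$parameters), unlist(x$parameter_names))
      vc <- if (is.null(x$vcov)) NULL
            else matrix(unlist(x$vcov), length(x$vcov), byrow = TRUE)
      surv_model(x$family, p, vcov = vc,
                 loglik = if (is.null(x$loglik)) NA_real_ else x$loglik,
                 n_events = if (is.null(x$n_events)) NA_integer_
                            else as.integer(x$n_events),
                 n_obs = if (is.null(x$n_obs)) NA_integer_
                         else as.integer(x$n_obs),
                 transition = if (is.null(x$transition)) NA_character_
                              else x$transition,
                 arm = if (is.null(x$arm)) NA_character_ else x$arm)
    } else lapply(x, de)
  }
  de(jsonlite::read_json(path))
}
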