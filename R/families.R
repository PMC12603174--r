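#' @importFrom stats AIC BIC coef logLik vcov predict simulate quantile
#'   optim qnorm pnorm rnorm runif rexp rbinom rpois rlnorm rgamma rbeta
#'   setNames aggregate uniroot sd var lm qbeta qgamma
NULL

# Registry of the six parametric time-to-event families.
# Parameters are stored on the unconstrained (fitting) scale; `trans`/`inv`
# map to the natural scale used by the d/p/h/H functions. The naming and
# transforms follow the dominant multistate-fitting convention so that
# published coefficient tables can be transcribed directly:
#   exponential  rate (log)
#   weibull      shape, scale (log, log);      S(t) = exp(-(t/scale)^shape)
#   gompertz     shape, rate (identity, log);  H(t) = rate/shape (e^{shape t}-1),
#                shape may be negative (hazard plateau, S(Inf) > 0)
#   loglogistic  shape, scale (log, log);      S(t) = 1/(1+(t/scale)^shape)
#   lognormal    meanlog, sdlog (identity, log)
#   gengamma     mu, sigma, Q (identity, log, identity); Q -> 0 is lognormal,
#                Q = 1 is Weibull with shape 1/sigma, scale exp(mu)
.families <- list(
  exponential = list(dist = "exp",      pars = "rate",
                     trans = "log"),
  weibull     = list(dist = "weibull",  pars = c("shape", "scale"),
                     trans = c("log", "log")),
  gompertz    = list(dist = "gompertz", pars = c("shape", "rate"),
                     trans = c("identity", "log")),
  loglogistic = list(dist = "llogis",   pars = c("shape", "scale"),
                     trans = c("log", "log")),
  lognormal   = list(dist = "lnorm",    pars = c("meanlog", "sdlog"),
                     trans = c("identity", "log")),
  gengamma    = list(dist = "gengamma", pars = c("mu", "sigma", "Q"),
                     trans = c("identity", "log", "identity"))
)

#' Supported parametric survival families
#'
#' The six standard extrapolation families recommended for survival
#' extrapolation in health-technology assessment: exponential, Weibull,
#' Gompertz, log-logistic, log-normal and generalized gamma.
#'
#' @return Character vector of family names.
#' @export
surv_families <- function() names(.families)

.family_info <- function(family) {
  family <- match.arg(family, names(.families))
  info <- .families[[family]]
  info$name <- family
  info$n_params <- length(info$pars)
  info
}

.to_natural <- function(x, trans) {
  y <- x
  y[trans == "log"] <- exp(x[trans == "log"])
  y
}

.to_unconstrained <- function(x, trans) {
  y <- x
  y[trans == "log"] <- log(x[trans == "log"])
  y
}

#' Construct a parametric survival model for one transition pathway
#'
#' Bundles a family with its parameter vector (natural scale), and optionally
#' a covariance matrix of the unconstrained parameters, a log-likelihood and
#' sample counts, into the object used throughout the transition engine,
#' probabilistic sensitivity analysis and scenario machinery.
#'
#' @param family One of \code{surv_families()}.
#' @param params Named or positional numeric vector of parameters on the
#'   natural scale, in the family's canonical order (see
#'   \code{\link{surv_families}}).
#' @param vcov Optional covariance matrix of the parameters on the
#'   unconstrained (log where positive-constrained) scale.
#' @param loglik,n_events,n_obs Optional fit metadata.
#' @param transition Optional transition label, e.g. \code{"TP1"}.
#' @param arm Optional arm label, \code{"intervention"} or \code{"comparator"}.
#' @return An object of class \code{surv_model}.
#' @examples
#' m <- surv_model("weibull", c(shape = 1.3, scale = 0.8))
#' surv_eval(m, c(0, 0.5, 1), "S")
#' @export
surv_model <- function(family, params, vcov = NULL, loglik = NA_real_,
                       n_events = NA_integer_, n_obs = NA_integer_,
                       transition = NA_character_, arm = NA_character_) {
  info <- .family_info(family)
  params <- as.numeric(params)
  if (length(params) != info$n_params)
    stop(sprintf("family '%s' takes %d parameter(s), got %d",
                 info$name, info$n_params, length(params)), call. = FALSE)
  if (any(!is.finite(params)))
    stop("non-finite survival parameters", call. = FALSE)
  pos <- info$trans == "log"
  if (any(params[pos] <= 0))
    stop(sprintf("parameters %s of family '%s' must be positive",
                 paste(info$pars[pos], collapse = ", "), info$name),
         call. = FALSE)
  names(params) <- info$pars
  coefs <- .to_unconstrained(params, info$trans)
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    if (!all(dim(vcov) == info$n_params))
      stop("vcov dimensions do not match the number of parameters",
           call. = FALSE)
    if (max(abs(vcov - t(vcov))) > 1e-8)
      stop("vcov must be symmetric", call. = FALSE)
    if (min(eigen(vcov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("vcov must be positive semi-definite", call. = FALSE)
    dimnames(vcov) <- list(info$pars, info$pars)
  }
  structure(list(family = info$name, params = params, coefficients = coefs,
                 vcov = vcov, loglik = loglik, n_events = n_events,
                 n_obs = n_obs, transition = transition, arm = arm),
            class = "surv_model")
}

# Rebuild a surv_model from unconstrained coefficients (PSA / DSA path).
surv_model_from_coef <- function(model, coefs) {
  info <- .family_info(model$family)
  surv_model(model$family, .to_natural(coefs, info$trans), vcov = model$vcov,
             transition = model$transition, arm = model$arm)
}

.dist_fun <- function(prefix, dist) {
  get(paste0(prefix, dist), envir = asNamespace("flexsurv"),
      inherits = TRUE)
}

#' Evaluate survival quantities of a parametric model
#'
#' Computes the survival function S, hazard h, cumulative hazard H or density
#' f of a \code{\link{surv_model}} at times since state entry.
#'
#' @param model A \code{surv_model}.
#' @param t Non-negative numeric vector of times (years since state entry).
#' @param quantity One of \code{"S"}, \code{"h"}, \code{"H"}, \code{"f"}.
#' @return Numeric vector, same length as \code{t}.
#' @export
surv_eval <- function(model, t, quantity = c("S", "h", "H", "f")) {
  stopifnot(inherits(model, "surv_model"))
  quantity <- match.arg(quantity)
  if (any(!is.finite(model$params)))
    stop("non-finite survival parameters", call. = FALSE)
  if (any(t < 0)) stop("negative time in survival evaluation", call. = FALSE)
  info <- .family_info(model$family)
  args <- c(list(t), as.list(unname(model$params)))
  names(args) <- c("x", info$pars)
  switch(quantity,
    S = {
      names(args)[1] <- "q"
      args$lower.tail <- FALSE
      do.call(.dist_fun("p", info$dist), args)
    },
    h = do.call(.dist_fun("h", info$dist), args),
    H = do.call(.dist_fun("H", info$dist), args),
    f = do.call(.dist_fun("d", info$dist), args))
}

#' @export
print.surv_model <- function(x, ...) {
  cat(sprintf("Parametric survival model: %s", x$family))
  if (!is.na(x$transition) || !is.na(x$arm))
    cat(sprintf("  [%s, %s]", x$transition, x$arm))
  cat("\n")
  print(signif(x$params, 5))
  if (is.finite(x$loglik))
    cat(sprintf("log-likelihood %.3f on %d events / %d observations\n",
                x$loglik, x$n_events, x$n_obs))
  invisible(x)
}

#' @export
coef.surv_model <- function(object, ...) object$coefficients

#' @export
vcov.surv_model <- function(object, ...) object$vcov

#' @export
logLik.surv_model <- function(object, ...) {
  structure(object$loglik, df = length(object$params),
            nobs = object$n_obs, class = "logLik")
}

#' Simulate event times from a parametric survival model
#'
#' Draws event times by inverse-transform of the cumulative hazard. Draws
#' whose cumulative hazard never reaches the exponential deviate within
#' \code{t_max} (possible for Gompertz with negative shape) are returned as
#' \code{Inf}; callers apply administrative censoring.
#'
#' @param object A \code{surv_model}.
#' @param nsim Number of draws.
#' @param seed Optional integer seed.
#' @param t_max Upper search bound in years.
#' @param ... Unused.
#' @return Numeric vector of length \code{nsim}.
#' @export
simulate.surv_model <- function(object, nsim = 1, seed = NULL,
                                t_max = 200, ...) {
  if (!is.null(seed)) set.seed(seed)
  e <- rexp(nsim)
  H_max <- surv_eval(object, t_max, "H")
  out <- rep(Inf, nsim)
  hit <- e < H_max
  if (any(hit)) {
    out[hit] <- vapply(e[hit], function(ei) {
      uniroot(function(s) surv_eval(object, s, "H") - ei,
              lower = 0, upper = t_max, tol = 1e-12)$root
    }, numeric(1))
  }
  out
}
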