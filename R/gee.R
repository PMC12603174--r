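# Generalized estimating equations for the longitudinal utility panel:
# gaussian identity-link marginal model with independence or exchangeable
# working correlation and cluster-robust (sandwich) standard errors.
# Implemented here directly (no GEE package is used); the independence /
# one-record-per-cluster case reduces exactly to ordinary least squares,
# which the test suite uses as an oracle.

#' Fit a marginal utility model by generalized estimating equations
#'
#' Linear mean model for repeated EQ-5D-3L-scale utility observations,
#' clustered by patient: by default
#' \code{utility ~ response + ae_leukocyte + ae_anemia + ae_platelet}, so the
#' intercept is the progression-free utility before treatment response, the
#' response coefficient the utility gain after response, and the
#' adverse-event coefficients the (negative) disutilities of active
#' leukocyte-deficiency, anemia and platelet-deficiency episodes.
#'
#' @param data data.frame with one row per patient-cycle; must contain the
#'   model variables and the cluster id column.
#' @param formula Mean-model formula (identity link).
#' @param id Name of the cluster (patient id) column.
#' @param corstr Working correlation: \code{"exchangeable"} (default) or
#'   \code{"independence"}.
#' @param tol,max_iter Convergence tolerance on the coefficient update and
#'   iteration cap.
#' @return Object of class \code{gee_fit} with robust (sandwich) covariance.
#' @export
fit_gee <- function(data,
                    formula = utility ~ response + ae_leukocyte +
                      ae_anemia + ae_platelet,
                    id = "id",
                    corstr = c("exchangeable", "independence"),
                    tol = 1e-10, max_iter = 100) {
  corstr <- match.arg(corstr)
  if (!id %in% names(data))
    stop("cluster id column '", id, "' not found", call. = FALSE)
  vars <- all.vars(formula)
  keep <- stats::complete.cases(data[, c(vars, id)])
  data <- data[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  cl <- data[[id]]
  if (length(unique(cl)) < 2)
    stop("at least two patients (clusters) are required", call. = FALSE)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  idx <- split(seq_along(y), cl)
  beta <- qr.coef(qrX, y)
  alpha <- 0
  N <- length(y)

  solve_beta <- function(alpha) {
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      yi <- y[ii]
      ni <- length(ii)
      if (corstr == "independence" || ni == 1L || alpha == 0) {
        A <- A + crossprod(Xi)
        b <- b + crossprod(Xi, yi)
      } else {
        # R^{-1} = (I - a/(1+(n-1)a) J) / (1-a) for exchangeable R
        g <- alpha / (1 + (ni - 1) * alpha)
        cs_x <- colSums(Xi)
        A <- A + (crossprod(Xi) - g * tcrossprod(cs_x)) / (1 - alpha)
        b <- b + (crossprod(Xi, yi) - g * cs_x * sum(yi)) / (1 - alpha)
      }
    }
    list(A = A, beta = drop(solve(A, b)))
  }

  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    phi <- sum(r^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ii in idx) {
        ni <- length(ii)
        if (ni > 1) {
          ri <- r[ii]
          num <- num + (sum(ri)^2 - sum(ri^2)) / 2
          den <- den + ni * (ni - 1) / 2
        }
      }
      alpha <- if (den > p && phi > 1e-300) num / ((den - p) * phi) else 0
      alpha <- max(min(alpha, 0.999), -0.099)
    }
    sol <- solve_beta(alpha)
    delta <- max(abs(sol$beta - beta))
    beta <- sol$beta
    if (delta < tol) break
  }
  converged <- delta < tol

  # sandwich: B^{-1} M B^{-1} with B = sum Xi' Ri^{-1} Xi,
  # M = sum Xi' Ri^{-1} ri ri' Ri^{-1} Xi (phi cancels)
  r <- y - drop(X %*% beta)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  score <- numeric(p)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    ri <- r[ii]
    ni <- length(ii)
    if (corstr == "independence" || ni == 1L || alpha == 0) {
      u <- crossprod(Xi, ri)
      B <- B + crossprod(Xi)
    } else {
      g <- alpha / (1 + (ni - 1) * alpha)
      cs_x <- colSums(Xi)
      u <- (crossprod(Xi, ri) - g * cs_x * sum(ri)) / (1 - alpha)
      B <- B + (crossprod(Xi) - g * tcrossprod(cs_x)) / (1 - alpha)
    }
    M <- M + tcrossprod(u)
    score <- score + u
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(coefficients = beta, vcov = V,
                 se = sqrt(diag(V)), alpha = alpha,
                 phi = sum(r^2) / (N - p), corstr = corstr,
                 n_clusters = length(idx), n_obs = N,
                 score = score, converged = converged,
                 formula = formula), class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE (gaussian, identity, %s) on %d obs in %d clusters\n",
              x$corstr, x$n_obs, x$n_clusters))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients,
               `Robust SE` = object$se, z = z,
               `Pr(>|z|)` = 2 * pnorm(-abs(z)),
               `2.5%` = object$coefficients - qnorm(0.975) * object$se,
               `97.5%` = object$coefficients + qnorm(0.975) * object$se)
  structure(list(table = tab, alpha = object$alpha, corstr = object$corstr,
                 n_clusters = object$n_clusters, n_obs = object$n_obs),
            class = "summary.gee_fit")
}

#' @export
print.summary.gee_fit <- function(x, ...) {
  cat(sprintf("GEE utility model (%s working correlation", x$corstr))
  if (x$corstr == "exchangeable") cat(sprintf(", alpha = %.3f", x$alpha))
  cat(sprintf(")\n%d observations in %d clusters\n", x$n_obs, x$n_clusters))
  stats::printCoefmat(x$table, digits = 4)
  invisible(x)
}

#' Extract utility parameters from a fitted GEE model
#'
#' @param fit A \code{\link{fit_gee}} result with the default design.
#' @return A utility-parameter list as used by \code{\link{cea_params}}:
#'   progression-free utility before/after response and the three
#'   adverse-event disutilities.
#' @export
utility_params_from_gee <- function(fit) {
  b <- coef(fit)
  need <- c("(Intercept)", "response", "ae_leukocyte", "ae_anemia",
            "ae_platelet")
  if (!all(need %in% names(b)))
    stop("fit does not use the standard utility design", call. = FALSE)
  list(u_pf_pre = unname(b["(Intercept)"]),
       u_pf_post = unname(b["(Intercept)"] + b["response"]),
       disutilities = c(leukocyte = unname(b["ae_leukocyte"]),
                        anemia = unname(b["ae_anemia"]),
                        platelet = unname(b["ae_platelet"])))
}

#' Response- and adverse-event-weighted progression-free utility
#'
#' \eqn{u = u_{pre} + (u_{post} - u_{pre})\, respProp +
#' \sum_c aePrev_c \, d_c}: the cycle's PF utility is the pre-response
#' utility shifted toward the post-response utility by the response
#' proportion, plus prevalence-weighted adverse-event disutilities
#' (\eqn{d_c \le 0}).
#'
#' @param utilities List with \code{u_pf_pre}, \code{u_pf_post} and named
#'   \code{disutilities} vector.
#' @param resp_prop Proportion responding in the cycle (scalar or vector).
#' @param ae_prev Adverse-event prevalence: vector named like
#'   \code{disutilities}, or a matrix with one row per cycle.
#' @return Per-cycle PF utility.
#' @export
cycle_weighted_pf_utility <- function(utilities, resp_prop, ae_prev) {
  d <- utilities$disutilities
  if (is.matrix(ae_prev)) {
    ae <- drop(ae_prev[, names(d), drop = FALSE] %*% d)
  } else {
    ae <- sum(ae_prev[names(d)] * d)
  }
  utilities$u_pf_pre +
    (utilities$u_pf_post - utilities$u_pf_pre) * resp_prop + ae
}
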