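# Decision-uncertainty machinery: parameter specifications with
# deterministic bounds and probabilistic distributions, one-way DSA with
# tornado ordering, Monte-Carlo PSA, acceptability curves and per-person
# expected value of perfect information.

# Stable per-parameter substream seed so adding a parameter does not shuffle
# the draws of the others.
.param_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * (seq_len(nchar(name)) * 131)) %% 1000003
  as.integer((as.numeric(master) * 1009 + h) %% 2147483647)
}

.beta_mom <- function(mean, sd) {
  v <- min(sd^2, 0.95 * mean * (1 - mean))
  if (v <= 0) return(NULL)
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

.scalar_spec <- function(name, group, base, low, high, get, set, sample) {
  list(name = name, group = group, kind = "scalar", base = base,
       low = low, high = high, get = get, set = set, sample = sample)
}

.assign_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
  } else {
    x[[path[[1]]]] <- .assign_path(x[[path[[1]]]], path[-1], value)
  }
  x
}

#' Parameter specifications for sensitivity analysis
#'
#' Enumerates every model input subject to uncertainty analysis, with its
#' deterministic bounds and probabilistic distribution. Bounds: survival
#' coefficients vary within their 95\% confidence intervals (from the fit
#' covariance); the fee-schedule conversion factor uses the supplied
#' regional (min, max) range; everything else varies by 25\% around the base
#' value (utilities capped at 1). Distributions (conventional CEA practice;
#' flagged as assumptions in the run manifest): beta for utilities and
#' proportions (method of moments, SE = 10\% of base, truncated to the valid
#' range), gamma for costs (SE = 25\% of base), negated gamma for
#' disutilities, multivariate normal on the unconstrained scale per
#' transition for survival coefficients. The willingness-to-pay threshold is
#' varied in the deterministic analysis only.
#'
#' @param params A \code{\link{cea_params}}.
#' @return List of parameter specifications (scalar entries and one
#'   multivariate-normal block per transition and arm).
#' @export
parameter_specs <- function(params) {
  specs <- list()
  add <- function(s) specs[[length(specs) + 1]] <<- s

  scalar_at <- function(name, group, path, low = NULL, high = NULL,
                        dist = group) {
    base <- Reduce(`[[`, path, params)
    if (is.null(low)) low <- 0.75 * base
    if (is.null(high)) high <- 1.25 * base
    get <- function(p) Reduce(`[[`, path, p)
    set <- function(p, value) .assign_path(p, path, value)
    sample <- switch(dist,
      utility = , proportion = {
        sh <- .beta_mom(base, 0.10 * abs(base))
        if (is.null(sh)) function(n) rep(base, n)
        else function(n) rbeta(n, sh["shape1"], sh["shape2"])
      },
      disutility = {
        if (base == 0) function(n) rep(0, n)
        else function(n) -rgamma(n, shape = 100, rate = 100 / abs(base))
      },
      cost = {
        if (base == 0) function(n) rep(0, n)
        else function(n) rgamma(n, shape = 16, rate = 16 / base)
      },
      threshold = function(n) rep(base, n))
    add(.scalar_spec(name, group, base, low, high, get, set, sample))
  }

  scalar_at("utility: PF pre-response", "utility",
            c("utilities", "u_pf_pre"),
            high = min(1, 1.25 * params$utilities$u_pf_pre))
  scalar_at("utility: PF post-response", "utility",
            c("utilities", "u_pf_post"),
            high = min(1, 1.25 * params$utilities$u_pf_post))
  scalar_at("utility: PD without BM", "utility",
            c("utilities", "u_pd_nobm"),
            high = min(1, 1.25 * params$utilities$u_pd_nobm))
  scalar_at("utility: PD with BM", "utility",
            c("utilities", "u_pd_bm"),
            high = min(1, 1.25 * params$utilities$u_pd_bm))
  for (cat in .ae_categories) {
    base <- params$utilities$disutilities[[cat]]
    scalar_at(paste0("disutility: ", cat), "utility",
              c("utilities", "disutilities", cat),
              low = 1.25 * base, high = 0.75 * base, dist = "disutility")
  }
  cost_items <- c("atezolizumab_per_cycle", "chemo_per_cycle",
                  "pf_nonmed_points", "pd_nobm_med", "pd_bm_med",
                  "pd_nobm_nonmed_points", "pd_bm_nonmed_points", "terminal")
  for (it in cost_items)
    scalar_at(paste0("cost: ", it), "cost", c("costs", it))
  for (cat in .ae_categories)
    scalar_at(paste0("cost: AE management, ", cat), "cost",
              c("costs", "ae_event_cost", cat))
  cf_range <- params$costs$conversion_factor_range
  scalar_at("conversion factor", "proportion",
            c("costs", "conversion_factor"),
            low = cf_range[1], high = cf_range[2], dist = "proportion")
  for (a in .arms) {
    if (!is.null(params$curves[[a]]$resp_max))
      scalar_at(paste0("response proportion plateau (", a, ")"),
                "proportion", c("curves", a, "resp_max"),
                high = min(1, 1.25 * params$curves[[a]]$resp_max))
  }
  scalar_at("willingness-to-pay threshold", "threshold",
            c("config", "wtp"), dist = "threshold")

  for (a in .arms) {
    for (tp in names(params$survival[[a]])) {
      m <- params$survival[[a]][[tp]]
      if (is.null(m$vcov)) next
      local({
        a_ <- a; tp_ <- tp; m_ <- m
        R <- chol(m_$vcov + diag(1e-12, nrow(m_$vcov)))
        add(list(
          name = sprintf("survival: %s (%s)", tp_, a_),
          group = "survival", kind = "mvn",
          base = m_$coefficients,
          se = sqrt(diag(m_$vcov)),
          get = function(p) p$survival[[a_]][[tp_]]$coefficients,
          set = function(p, value) {
            p$survival[[a_]][[tp_]] <- surv_model_from_coef(m_, value)
            p
          },
          sample = function(n) {
            z <- matrix(rnorm(n * length(m_$coefficients)), n)
            sweep(z %*% R, 2, m_$coefficients, `+`)
          }))
      })
    }
  }
  specs
}

#' One-way deterministic sensitivity analysis with tornado ordering
#'
#' Runs the full model twice per parameter (at its low and high bound,
#' all others at base) and tabulates the resulting ICER and INMB, ordered
#' by descending INMB range (the tornado order). Multivariate survival
#' blocks are varied one coefficient at a time within its 95\% confidence
#' interval. A model failure at a bound flags the row rather than dropping
#' it.
#'
#' @param params A \code{\link{cea_params}}.
#' @param specs Parameter specifications; default
#'   \code{\link{parameter_specs}}.
#' @return Object of class \code{cea_dsa}: data.frame with columns
#'   parameter, group, low, high, icer_low/high, inmb_low/high, inmb_range,
#'   failed.
#' @export
one_way_dsa <- function(params, specs = parameter_specs(params)) {
  base <- run_cea(params)
  rows <- list()
  eval_at <- function(spec, value) {
    tryCatch({
      r <- run_cea(spec$set(params, value))
      # threshold changes affect INMB through the modified config
      list(icer = r$summary$icer_qaly$value, inmb = r$summary$inmb_qaly,
           failed = FALSE)
    }, error = function(e) list(icer = NA_real_, inmb = NA_real_,
                                failed = TRUE))
  }
  for (spec in specs) {
    if (spec$kind == "scalar") {
      lo <- eval_at(spec, spec$low)
      hi <- eval_at(spec, spec$high)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = spec$name, group = spec$group,
        low = spec$low, high = spec$high,
        icer_low = lo$icer, icer_high = hi$icer,
        inmb_low = lo$inmb, inmb_high = hi$inmb,
        failed = lo$failed || hi$failed)
    } else {
      for (i in seq_along(spec$base)) {
        vlo <- vhi <- spec$base
        vlo[i] <- spec$base[i] - qnorm(0.975) * spec$se[i]
        vhi[i] <- spec$base[i] + qnorm(0.975) * spec$se[i]
        lo <- eval_at(spec, vlo)
        hi <- eval_at(spec, vhi)
        rows[[length(rows) + 1]] <- data.frame(
          parameter = paste0(spec$name, ": ", names(spec$base)[i]),
          group = spec$group, low = vlo[i], high = vhi[i],
          icer_low = lo$icer, icer_high = hi$icer,
          inmb_low = lo$inmb, inmb_high = hi$inmb,
          failed = lo$failed || hi$failed)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$inmb_range <- abs(tab$inmb_high - tab$inmb_low)
  tab <- tab[order(-tab$inmb_range), ]
  rownames(tab) <- NULL
  structure(list(table = tab, base_icer = base$summary$icer_qaly$value,
                 base_inmb = base$summary$inmb_qaly,
                 wtp = params$config$wtp), class = "cea_dsa")
}

#' @export
print.cea_dsa <- function(x, n = 10, ...) {
  cat(sprintf("One-way DSA (base ICER %s, base INMB %s); top %d of %d:\n",
              .fmt_money(x$base_icer), .fmt_money(x$base_inmb),
              min(n, nrow(x$table)), nrow(x$table)))
  print(utils::head(x$table[, c("parameter", "inmb_low", "inmb_high",
                                "inmb_range")], n), digits = 6)
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each parameter is drawn
#' from its distribution (see \code{\link{parameter_specs}}) in its own
#' deterministic substream of the master seed, and the full model is run per
#' draw.
#'
#' @param params A \code{\link{cea_params}}.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Master seed.
#' @param specs Parameter specifications.
#' @return Object of class \code{cea_psa}: per-draw (cost, QALY, LY) per
#'   strategy and increments, plus the threshold and seed.
#' @export
run_psa <- function(params, n_draws = 5000, seed = 1,
                    specs = parameter_specs(params)) {
  stopifnot(n_draws >= 1)
  specs <- Filter(function(s) s$group != "threshold", specs)
  draws <- lapply(specs, function(s) {
    set.seed(.param_seed(seed, s$name))
    d <- s$sample(n_draws)
    if (s$kind == "scalar") d <- matrix(d, ncol = 1)
    if (any(!is.finite(d)))
      stop("invalid draws for parameter '", s$name, "'", call. = FALSE)
    d
  })
  out <- matrix(NA_real_, n_draws, 6,
                dimnames = list(NULL, c("cost_int", "qaly_int", "ly_int",
                                        "cost_comp", "qaly_comp", "ly_comp")))
  for (i in seq_len(n_draws)) {
    p <- params
    for (j in seq_along(specs)) {
      v <- draws[[j]][i, ]
      p <- specs[[j]]$set(p, if (specs[[j]]$kind == "scalar") v[1] else v)
    }
    r <- run_cea(p)
    pa <- r$per_arm
    out[i, ] <- c(pa$cost[pa$arm == "intervention"],
                  pa$qaly[pa$arm == "intervention"],
                  pa$ly[pa$arm == "intervention"],
                  pa$cost[pa$arm == "comparator"],
                  pa$qaly[pa$arm == "comparator"],
                  pa$ly[pa$arm == "comparator"])
  }
  d <- as.data.frame(out)
  d$delta_cost <- d$cost_int - d$cost_comp
  d$delta_qaly <- d$qaly_int - d$qaly_comp
  structure(list(draws = d, n_draws = n_draws, seed = seed,
                 wtp = params$config$wtp), class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("PSA: %d draws (seed %d)\n", x$n_draws, x$seed))
  cat(sprintf("  P(cost-effective at WTP %s) = %.2f%%\n",
              .fmt_money(x$wtp), 100 * s$p_ce))
  cat(sprintf("  quadrant shares: NE %.2f%%  NW %.2f%%  SE %.2f%%  SW %.2f%%\n",
              100 * s$quadrants["NE"], 100 * s$quadrants["NW"],
              100 * s$quadrants["SE"], 100 * s$quadrants["SW"]))
  cat(sprintf("  per-person EVPI = %s\n", .fmt_money(s$evpi)))
  invisible(x)
}

#' @export
summary.cea_psa <- function(object, wtp = object$wtp, ...) {
  d <- object$draws
  quad <- ce_quadrant(d$delta_cost, d$delta_qaly)
  list(p_ce = mean(inmb(d$delta_cost, d$delta_qaly, wtp) > 0),
       quadrants = vapply(c(NE = "NE", NW = "NW", SE = "SE", SW = "SW"),
                          function(q) mean(quad == q), numeric(1)),
       evpi = evpi(object, wtp),
       mean_delta_cost = mean(d$delta_cost),
       mean_delta_qaly = mean(d$delta_qaly))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of draws in which the
#' intervention's incremental net monetary benefit is positive.
#'
#' @param psa A \code{\link{run_psa}} result.
#' @param wtp_grid Numeric vector of thresholds.
#' @return data.frame with columns \code{wtp}, \code{p_ce}.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2 * psa$wtp, length.out = 101)) {
  stopifnot(length(wtp_grid) >= 1, nrow(psa$draws) >= 1)
  d <- psa$draws
  p <- vapply(wtp_grid,
              function(l) mean(l * d$delta_qaly - d$delta_cost > 0),
              numeric(1))
  data.frame(wtp = wtp_grid, p_ce = p)
}

#' Per-person expected value of perfect information
#'
#' The mean over draws of the best-per-draw net monetary benefit minus the
#' net monetary benefit of the strategy that is best on average:
#' \eqn{E_\theta[\max_s NMB_s(\theta)] - \max_s E_\theta[NMB_s(\theta)]}.
#' Always non-negative; zero exactly when one strategy is optimal in every
#' draw.
#'
#' @param psa A \code{\link{run_psa}} result, or a matrix/data.frame of
#'   per-draw net monetary benefits with one column per strategy.
#' @param wtp Willingness-to-pay threshold (ignored when an NMB matrix is
#'   supplied directly).
#' @return Scalar NT$ per person.
#' @export
evpi <- function(psa, wtp = NULL) {
  if (inherits(psa, "cea_psa")) {
    if (is.null(wtp)) wtp <- psa$wtp
    d <- psa$draws
    nmb <- cbind(intervention = wtp * d$qaly_int - d$cost_int,
                 comparator = wtp * d$qaly_comp - d$cost_comp)
  } else {
    nmb <- as.matrix(psa)
    if (ncol(nmb) < 2)
      stop("EVPI needs at least two strategies", call. = FALSE)
  }
  mean(do.call(pmax, as.data.frame(nmb))) - max(colMeans(nmb))
}

#' Write PSA draws to CSV
#'
#' @param psa A \code{cea_psa}.
#' @param path Output path.
#' @export
write_psa_csv <- function(psa, path) {
  utils::write.csv(psa$draws, path, row.names = FALSE)
  invisible(path)
}
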