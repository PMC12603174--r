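# Shared fixtures built in code at test time.

# Random valid parameter vectors per family, for property-style loops.
random_surv_model <- function(family) {
  switch(family,
    exponential = surv_model("exponential", c(rate = runif(1, 0.1, 3))),
    weibull = surv_model("weibull", c(shape = runif(1, 0.5, 2.5),
                                      scale = runif(1, 0.2, 3))),
    gompertz = surv_model("gompertz", c(shape = runif(1, -1, 1.5),
                                        rate = runif(1, 0.1, 2))),
    loglogistic = surv_model("loglogistic", c(shape = runif(1, 0.6, 3),
                                              scale = runif(1, 0.2, 3))),
    lognormal = surv_model("lognormal", c(meanlog = runif(1, -1.5, 1),
                                          sdlog = runif(1, 0.3, 1.5))),
    gengamma = surv_model("gengamma", c(mu = runif(1, -1.5, 1),
                                        sigma = runif(1, 0.4, 1.2),
                                        Q = runif(1, -1, 1.5))))
}

# Small parameter set with a short horizon, for fast model-level tests.
small_params <- function(horizon_years = 5, ...) {
  default_params(cea_config(horizon_years = horizon_years, ...))
}

# Right-censored weibull sample with administrative censoring tuned to a
# target censoring fraction.
sim_censored_weibull <- function(n, shape, scale, cens_q = 0.8) {
  t <- rweibull(n, shape, scale)
  cens <- quantile(t, cens_q)
  data.frame(time_years = pmin(t, cens), event = as.integer(t < cens))
}
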