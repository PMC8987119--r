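# Prior specifications.  A prior entry is list(family, ...hyperparameters);
# families used: "normal" (mean, sd), "exponential" (rate), "uniform"
# (lower, upper), "logistic" (location 0, scale 1; the logit-scale image of a
# flat Beta(1,1) prior on a probability).

prior_logdens <- function(value, spec) {
  switch(spec$family,
    normal = dnorm(value, spec$mean, spec$sd, log = TRUE),
    exponential = stats::dexp(value, rate = spec$rate, log = TRUE),
    uniform = stats::dunif(value, spec$lower, spec$upper, log = TRUE),
    logistic = dlogis(value, 0, 1, log = TRUE),
    stop("unknown prior family '", spec$family, "'")
  )
}

#' Default priors for the growth model
#'
#' Weakly informative defaults: normal priors on the asymptote scale wide
#' enough to cover any plausible snake length, diffuse normals on the log
#' growth coefficient, and exponential priors on all standard deviations
#' (rate 1 for log-scale effect SDs, rate 0.1 for SDs measured in mm).
#'
#' @param ... named overrides; each value a `list(family = , ...)`.
#' @return named list of prior specifications.
#' @export
growth_priors <- function(...) {
  defaults <- list(
    upsilon_f = list(family = "normal", mean = 750, sd = 200),
    theta_m = list(family = "normal", mean = 0, sd = 200),
    mu_f = list(family = "normal", mean = 0, sd = 10),
    beta_m = list(family = "normal", mean = 0, sd = 10),
    sigma_k_year = list(family = "exponential", rate = 1),
    sigma_k_site = list(family = "exponential", rate = 1),
    sigma_k_indiv = list(family = "exponential", rate = 1),
    sigma_a_site = list(family = "exponential", rate = 0.1),
    sigma_e = list(family = "exponential", rate = 0.1)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  stop_if(length(unknown) > 0, "unknown growth prior(s): ",
          paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  defaults
}

#' MCMC configuration
#'
#' @param chains number of chains (default 4).
#' @param draws retained draws per chain after warmup (default 5000).
#' @param warmup adaptation iterations discarded per chain (default 2000).
#' @param thin thinning interval (default 1).
#' @return list of MCMC settings.
#' @export
mcmc_config <- function(chains = 4L, draws = 5000L, warmup = 2000L,
                        thin = 1L) {
  stop_if(chains < 1 || draws < 1 || warmup < 0 || thin < 1,
          "invalid MCMC configuration")
  list(chains = as.integer(chains), draws = as.integer(draws),
       warmup = as.integer(warmup), thin = as.integer(thin))
}

#' Default priors for the robust-design model
#'
#' Mean-probability intercepts get flat Beta(1,1) priors on the probability
#' scale, expressed as standard-logistic priors on the logit intercepts;
#' survey-covariate slopes get standard normals; all standard deviations get
#' Exp(1); the growth/survival annual-effect correlation gets Uniform(-1, 1).
#' Growth-block priors are normal approximations carried over from a fitted
#' stage-1 growth model (see [stage1_growth_priors()]); when no stage-1 fit
#' is supplied the growth block falls back to the diffuse [growth_priors()].
#'
#' @param growth_stage1 optional `vb_growth_fit` whose posterior becomes the
#'   growth-block prior.
#' @param inflation factor (>= 1) by which stage-1 posterior SDs are widened
#'   (default 2).
#' @param sigma_b_rate exponential rate for the spline shrinkage SDs
#'   (default 1).
#' @return named list of prior specifications.
#' @export
cmr_priors <- function(growth_stage1 = NULL, inflation = 2,
                       sigma_b_rate = 1) {
  stop_if(inflation < 1, "prior inflation factor must be >= 1")
  pr <- list(
    intercept = list(family = "logistic"),
    delta_p = list(family = "normal", mean = 0, sd = 1),
    lambda_gamma = list(family = "normal", mean = 0, sd = 1),
    sigma_phi_year = list(family = "exponential", rate = 1),
    sigma_p_year = list(family = "exponential", rate = 1),
    sigma_gamma_year = list(family = "exponential", rate = 1),
    sigma_b = list(family = "exponential", rate = sigma_b_rate),
    rho_k_phi = list(family = "uniform", lower = -1, upper = 1),
    inflation = inflation
  )
  pr$growth <- stage1_growth_priors(growth_stage1, inflation)
  pr
}

#' Normal approximation of a stage-1 growth posterior
#'
#' Location parameters are transferred as `N(posterior mean, posterior SD *
#' inflation)`; SD parameters are transferred on the log scale with the same
#' inflation (delta-method SD).  The widening acknowledges that the stage-1
#' posterior is itself an estimate.
#'
#' @param fit a `vb_growth_fit`, or `NULL` for diffuse defaults.
#' @param inflation SD inflation factor.
#' @return named list of prior specifications for the CMR growth block.
#' @export
stage1_growth_priors <- function(fit, inflation = 2) {
  if (is.null(fit)) {
    gp <- growth_priors()
    return(list(
      upsilon_f = gp$upsilon_f, theta_m = gp$theta_m,
      mu_f = gp$mu_f, beta_m = gp$beta_m,
      eta = list(family = "normal", mean = 0, sd = 50),
      alpha = list(family = "normal", mean = 0, sd = 1),
      log_sigma_e = list(family = "normal", mean = log(20), sd = 1),
      log_sigma_k_year = list(family = "normal", mean = log(0.2), sd = 1)
    ))
  }
  stop_if(!inherits(fit, "vb_growth_fit"), "expected a vb_growth_fit")
  sm <- summary_table(fit$draws)
  get <- function(p) sm[sm$parameter == p, ]
  loc <- function(p) {
    row <- get(p)
    list(family = "normal", mean = row$mean, sd = row$sd * inflation)
  }
  logn <- function(p) {
    row <- get(p)
    list(family = "normal", mean = log(row$mean),
         sd = (row$sd / row$mean) * inflation)
  }
  eta_labels <- grep("^eta\\[", sm$parameter, value = TRUE)
  alpha_labels <- grep("^alpha\\[", sm$parameter, value = TRUE)
  list(
    upsilon_f = loc("upsilon_f"), theta_m = loc("theta_m"),
    mu_f = loc("mu_f"), beta_m = loc("beta_m"),
    eta = setNames(lapply(eta_labels, loc), eta_labels),
    alpha = setNames(lapply(alpha_labels, loc), alpha_labels),
    log_sigma_e = logn("sigma_e"),
    log_sigma_k_year = logn("sigma_k_year")
  )
}
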