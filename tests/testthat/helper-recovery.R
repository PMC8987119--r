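# Long-running shared fixtures: the parameter-recovery study and the
# spline-behavior fits.  Each is computed once per test run (results are
# memoized in the helper environment) and reused by several tests.

recovery_replicate <- function(r) {
  # growth survey: five sites, as in the emulated study's growth data
  cfg_g <- simulation_config(
    sites = c("N", "C", "S", "I", "P"),
    start_year = c(N = 2014, C = 2009, S = 2014, I = 2011, P = 2015),
    n_years = c(N = 4, C = 7, S = 4, I = 5, P = 4),
    occasions_per_year = 15L,
    n_individuals = c(N = 45, C = 70, S = 45, I = 50, P = 40))
  gd <- simulate_remeasurement_events(cfg_g, seed = 1000 + r)
  inc <- suppressWarnings(build_growth_increments(gd$events))
  gfit <- fit_growth(inc, mcmc = mcmc_config(chains = 2, draws = 1000,
                                             warmup = 900),
                     seed = 1000 + r)
  cfg <- simulation_config(
    n_years = c(C = 5, I = 4), start_year = c(C = 2010, I = 2011),
    occasions_per_year = 15L, n_individuals = c(C = 180, I = 100))
  sim <- simulate_study(cfg, seed = 2000 + r)
  ds <- filter_cmr_individuals(sim$dataset)
  fit <- fit_cmr(ds, growth_stage1 = gfit,
                 mcmc = mcmc_config(chains = 2, draws = 700, warmup = 600),
                 seed = 3000 + r)
  pg <- ppc_growth(gfit, n_draws = 300, seed = 4000 + r)
  pf <- ppc_cmr(fit, n_draws = 200, seed = 5000 + r)
  list(r = r, n_inc = nrow(inc),
       n_growth_ind = length(unique(inc$individual_id)),
       N = nrow(ds$individuals),
       gsm = summary_table(gfit$draws,
                           c("upsilon_f", "theta_m", "mu_f", "sigma_e")),
       csm = summary_table(fit$draws),
       scale = fit$spline_spec$scale, cfg = cfg,
       p_growth = pg$p_value, p_ft = pf$p_value)
}

recovery_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lapply(1:10, recovery_replicate)
    cache
  }
})

ci_covers <- function(sm, lab, truth) {
  r <- sm[sm$parameter == lab, ]
  truth >= r$q2.5 & truth <= r$q97.5
}

# spline-behavior fits: one with the penalized smooth free (default
# flat-then-declining truth curve), one with the shrinkage SD pinned near
# zero so the smooth collapses to a line
spline_fits <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(
      n_years = c(C = 7, I = 5), start_year = c(C = 2009, I = 2011),
      occasions_per_year = 20L, n_individuals = c(C = 320, I = 160))
    sim <- simulate_study(cfg, seed = 4242)
    ds <- filter_cmr_individuals(sim$dataset)
    free <- fit_cmr(ds, mcmc = mcmc_config(chains = 2, draws = 700,
                                           warmup = 600), seed = 11)
    pinned <- fit_cmr(ds, mcmc = mcmc_config(chains = 1, draws = 500,
                                             warmup = 500), seed = 12,
                      init = list(sigma_b_phi = 1e-6),
                      fix = "sigma_b_phi")
    cache <<- list(cfg = cfg, dataset = ds, free = free, pinned = pinned)
    cache
  }
})
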