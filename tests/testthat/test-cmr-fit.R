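cmr_fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- tiny_cmr_dataset(seed = 88)
      cache <<- fit_cmr(ds, mcmc = mcmc_config(chains = 2, draws = 200,
                                               warmup = 200), seed = 44)
    }
    cache
  }
})

test_that("robust-design fits are deterministic given seed and config", {
  ds <- tiny_cmr_dataset(seed = 89)
  f1 <- fit_cmr(ds, mcmc = mcmc_config(chains = 1, draws = 80,
                                       warmup = 80), seed = 55)
  f2 <- fit_cmr(ds, mcmc = mcmc_config(chains = 1, draws = 80,
                                       warmup = 80), seed = 55)
  expect_identical(draws_matrix(f1$draws), draws_matrix(f2$draws))
})

test_that("the joint fit exposes the full parameter structure", {
  fit <- cmr_fit_small()
  labs <- fit$draws$parameters
  for (pat in c("^pi_phi\\[", "^o_p\\[", "^zeta_gamma\\[", "^delta_p\\[",
                "^b_phi\\[", "^b_p\\[", "^omega\\[", "^nu\\[", "^xi\\[",
                "^zeta_k\\[", "^phi_mean\\[", "^p_mean\\[",
                "^gamma_mean\\[")) {
    expect_true(any(grepl(pat, labs)), info = pat)
  }
  expect_true(all(c("lambda_gamma", "rho_k_phi", "sigma_phi_year",
                    "upsilon_f", "sigma_e") %in% labs))
  dm <- draws_matrix(fit$draws)
  # derived mean rates are exact transforms of the intercepts and smooth
  bref <- drop(spline_basis(fit$model_data$x_ref, fit$spline_spec,
                            standardized = TRUE))
  G <- fit$spline_spec$n_knots
  fref <- dm[, c("q_phi", paste0("b_phi[", 1:G, "]"))] %*% bref
  expect_equal(dm[, "phi_mean[female.C]"],
               unname(plogis(dm[, "pi_phi[female.C]"] + drop(fref))),
               tolerance = 1e-12)
  expect_true(all(dm[, "rho_k_phi"] > -1 & dm[, "rho_k_phi"] < 1))
  expect_true(all(dm[, grep("^sigma", colnames(dm))] > 0))
  # latent male indicators are binary; latent sizes stay in a snake range
  mcols <- grep("^male\\[", colnames(dm), value = TRUE)
  if (length(mcols)) expect_true(all(dm[, mcols] %in% c(0, 1)))
  scols <- grep("^svl0\\[", colnames(dm), value = TRUE)
  if (length(scols)) {
    expect_true(all(dm[, scols] > 0 & dm[, scols] < 1000))
  }
})

test_that("Freeman-Tukey PPC runs in both availability modes,
           reproducibly", {
  fit <- cmr_fit_small()
  c1 <- ppc_cmr(fit, n_draws = 100, mode = "conditional", seed = 8)
  c2 <- ppc_cmr(fit, n_draws = 100, mode = "conditional", seed = 8)
  expect_equal(c1$t_replicate, c2$t_replicate)
  m1 <- ppc_cmr(fit, n_draws = 100, mode = "marginal", seed = 8)
  expect_true(all(c1$t_observed >= 0))
  expect_true(all(m1$t_observed >= 0))
  expect_gte(c1$p_value, 0); expect_lte(c1$p_value, 1)
})

test_that("curves from a fitted model agree with the reference summaries", {
  fit <- cmr_fit_small()
  ref <- fit$model_data$reference_svl
  cv <- curve_vs_svl(fit, "survival", ref, "female", "C")
  sm <- summary_table(fit$draws, "phi_mean[female.C]")
  expect_equal(cv$mean, sm$mean, tolerance = 1e-9)
  expect_equal(cv$lower, sm$q2.5, tolerance = 1e-9)
})
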