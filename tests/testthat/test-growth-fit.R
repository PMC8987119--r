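# A small shared fit keeps these tests fast; deeper inference checks live
# in the recovery study used by the acceptance suite.
growth_fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      inc <- small_growth_increments(seed = 77)
      cache <<- fit_growth(inc, mcmc = mcmc_config(chains = 2, draws = 300,
                                                   warmup = 300),
                           seed = 19)
    }
    cache
  }
})

test_that("fits are deterministic given seed and config", {
  inc <- small_growth_increments(seed = 78, n_c = 20, n_i = 12)
  f1 <- fit_growth(inc, mcmc = mcmc_config(chains = 1, draws = 100,
                                           warmup = 100), seed = 33)
  f2 <- fit_growth(inc, mcmc = mcmc_config(chains = 1, draws = 100,
                                           warmup = 100), seed = 33)
  expect_identical(draws_matrix(f1$draws), draws_matrix(f2$draws))
  f3 <- fit_growth(inc, mcmc = mcmc_config(chains = 1, draws = 100,
                                           warmup = 100), seed = 34)
  expect_false(identical(draws_matrix(f1$draws), draws_matrix(f3$draws)))
})

test_that("derived male means are exact linear combinations per draw", {
  fit <- growth_fit_small()
  dm <- draws_matrix(fit$draws)
  expect_equal(dm[, "mu_a_m"], dm[, "upsilon_f"] + dm[, "theta_m"],
               tolerance = 1e-12)
  expect_equal(dm[, "mu_k_m"], dm[, "mu_f"] + dm[, "beta_m"],
               tolerance = 1e-12)
  expect_equal(mean(dm[, "mu_a_m"]),
               mean(dm[, "upsilon_f"]) + mean(dm[, "theta_m"]),
               tolerance = 1e-12)
})

test_that("the fit carries labeled chains, SDs, and a convergence report", {
  fit <- growth_fit_small()
  expect_s3_class(fit$draws, "posterior_draws")
  expect_true(all(c("upsilon_f", "sigma_e", "sigma_k_indiv") %in%
                    fit$draws$parameters))
  expect_true(all(draws_of(fit$draws, "sigma_e") > 0))
  expect_true(is.finite(fit$convergence$max_rhat))
  # unknown-sex individuals get a latent male indicator in {0, 1}
  mcols <- grep("^male\\[", fit$draws$parameters, value = TRUE)
  if (length(mcols)) {
    mv <- draws_of(fit$draws, mcols[1])
    expect_true(all(mv %in% c(0, 1)))
  }
})

test_that("size-at-age projections anchor at the neonate distribution and
           approach sex-specific asymptotes", {
  # constant draws at typical posterior means make the projection
  # deterministic up to the neonate draw
  labs <- c("upsilon_f", "theta_m", "mu_f", "beta_m")
  m <- matrix(rep(c(737.23, -186.57, 5.55, 0.34), each = 400), 400, 4,
              dimnames = list(NULL, labs))
  fake <- structure(list(draws = posterior_draws(list(m))),
                    class = "vb_growth_fit")
  f <- project_size_at_age(fake, "female", ages = 0:12, seed = 2)
  m_ <- project_size_at_age(fake, "male", ages = 0:12, seed = 2)
  expect_lt(abs(f$median[1] - 165), 2)
  expect_lt(abs(f$mean[13] - 737.23), 25)
  expect_lt(abs(m_$mean[13] - 550.66), 10)
  # males near their asymptote by ages 4-5; females still short of theirs
  male_frac5 <- m_$mean[6] / 550.66
  female_frac5 <- f$mean[6] / 737.23
  expect_gt(male_frac5, 0.93)
  expect_lt(female_frac5, 0.90)
  # females approach the asymptote only around ages 7-8
  expect_gt(f$mean[9] / 737.23, 0.90)
  expect_error(project_size_at_age(fake, "female", ages = c(3, 1)),
               "ascending")
})

test_that("expected lengths reconstructed from a draw match the model", {
  fit <- growth_fit_small()
  dat <- fit$model_data
  dm <- draws_matrix(fit$draws)
  mu <- vbcmr:::growth_expected_at(dm[5, ], dat)
  expect_equal(length(mu), dat$n_inc)
  expect_true(all(is.finite(mu)))
  # zero random effects reduce to the closed-form curve
  draw <- dm[5, ]
  draw[grep("^(eta|alpha|zeta|iota)\\[", names(draw))] <- 0
  mu0 <- vbcmr:::growth_expected_at(draw, dat)
  j <- 1
  male <- as.numeric(dat$sex[dat$ind[j]] == "male")
  if (dat$sex[dat$ind[j]] == "unknown") {
    male <- draw[[paste0("male[", dat$ids[dat$ind[j]], "]")]]
  }
  a <- draw[["upsilon_f"]] + draw[["theta_m"]] * male
  k <- exp(draw[["mu_f"]] + draw[["beta_m"]] * male)
  w <- sum(dat$dt_mat[j, ])
  expect_equal(mu0[j], a - (a - dat$l_start[j]) * exp(-k * w / a),
               tolerance = 1e-9)
})
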