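test_that("linear predictors compose additively on the logit scale", {
  spec <- spline_spec(runif(60, 250, 700), n_knots = 5, degree = 3)
  zero <- list(q = 0, b = rep(0, 5))
  expect_equal(survival_logit(0.2, 0, zero, spec), 0.5)
  expect_equal(survival_logit(0.2, 0, zero, spec, year_effect = 1),
               plogis(1))
  expect_equal(
    qlogis(survival_logit(0.2, 0.66, zero, spec, year_effect = 1)) -
      qlogis(survival_logit(0.2, 0.66, zero, spec)), 1)
  # back-transformed mean survival of females at a typical site
  expect_equal(survival_logit(0, qlogis(0.66), zero, spec), 0.66)
  # capture probability: slope acts per covariate unit, precip flips by its
  # coefficient exactly
  W0 <- c(0, 0, 0, 0); W1 <- c(1, 0, 0, 0); Wp <- c(0, 0, 0, 1)
  delta <- c(0.183, -0.214, -0.265, -0.652)
  expect_equal(capture_logit(0, 0, delta, W0, zero, spec), 0.5)
  expect_equal(qlogis(capture_logit(0, 0, delta, W1, zero, spec)), 0.183)
  expect_equal(qlogis(capture_logit(0, 0, delta, Wp, zero, spec)), -0.652)
  expect_error(capture_logit(0, 0, delta, c(1, NA, 0, 0), zero, spec),
               "missing")
  # availability: linear and monotone in size when lambda > 0
  expect_equal(availability_logit(0, qlogis(0.33), 0.5), 0.33)
  svls <- seq(-2, 2, 0.5)
  g <- availability_logit(svls, 0.2, 0.7)
  expect_true(all(diff(g) > 0))
  expect_equal(availability_logit(1.3, 0.2, 0), plogis(0.2))
})

test_that("transition matrix is row-stochastic with absorbing death", {
  tm <- transition_matrix(0.66, 0.33)
  expect_equal(unname(rowSums(tm)), c(1, 1, 1))
  expect_equal(unname(tm[1, ]), c(0.2178, 0.4422, 0.34))
  expect_equal(tm[1, ], tm[2, ])  # random emigration
  expect_equal(unname(tm[3, ]), c(0, 0, 1))
  dead <- transition_matrix(0, 0.5)
  expect_equal(unname(dead[1, ]), c(0, 0, 1))
  expect_error(transition_matrix(1.2, 0.5), "\\[0, 1\\]")
})

test_that("emissions implement the known-available rule", {
  expect_equal(emission_probability("available", c(1, 0), c(0.5, 0.5)),
               0.25)
  expect_equal(emission_probability("unavailable", c(0, 1), c(0.5, 0.5)), 0)
  expect_equal(emission_probability("dead", c(0, 0), c(0.9, 0.9)), 1)
  # perturbing p leaves the emission of a non-detected unavailable
  # individual unchanged at 1
  expect_equal(emission_probability("unavailable", c(0, 0), c(0.1, 0.9)),
               emission_probability("unavailable", c(0, 0), c(0.5, 0.2)))
  expect_error(emission_probability("available", c(1, 0), 0.5), "length")
})

test_that("forward likelihood matches hand-enumerated toy histories", {
  # release, then one primary with one occasion
  expect_equal(exp(history_log_likelihood(list(1, 0), list(0.5, 0.5),
                                          0.5, 0.5)),
               0.5 * 0.5 * 0.5 + 0.5 * 0.5 + 0.5)
  expect_equal(exp(history_log_likelihood(list(1, 1), list(0.5, 0.5),
                                          0.5, 0.5)), 0.125)
  # p = 0 after release: the all-zero history is certain
  expect_equal(history_log_likelihood(list(c(1, 0), c(0, 0)),
                                      list(c(0.4, 0), c(0, 0)), 0.7, 0.4),
               0)
  expect_error(history_log_likelihood(list(c(0, 0), c(1, 0)),
                                      list(c(0.4, 0.4), c(0.4, 0.4)),
                                      0.7, 0.4),
               "first-capture")
})

test_that("with gamma = 1 and one occasion the model collapses to CJS", {
  set.seed(7)
  for (rep in 1:50) {
    Tn <- sample(3:6, 1)
    phi <- runif(Tn - 1, 0.3, 0.95)
    p <- runif(Tn, 0.2, 0.9)
    det <- c(1, rbinom(Tn - 1, 1, 0.5))
    ll <- history_log_likelihood(as.list(det), as.list(p),
                                 phi, rep(1, Tn - 1))
    expect_equal(ll, cjs_ll(det, phi, p), tolerance = 1e-12)
  }
})

test_that("latent size propagation composes the growth kernel", {
  k <- c("2010" = 200, "2011" = 250)
  mids <- as.Date(c("2010-05-01", "2011-05-01", "2012-05-01"))
  path <- propagate_latent_size(300, 700, k, mids)
  expect_equal(path[1], 300)
  d1 <- as.numeric(mids[2] - mids[1]); d2 <- as.numeric(mids[3] - mids[2])
  expect_equal(path[2], vb_expected_length(300, 700, 200, d1 / 365.25))
  expect_equal(path[3], vb_expected_length(path[2], 700, 250, d2 / 365.25))
  expect_true(all(diff(path) > 0))
  # a two-year jump uses the starting year's coefficient over the full gap
  two <- propagate_latent_size(300, 700, k, mids[c(1, 3)])
  expect_equal(two[2], vb_expected_length(300, 700, 200,
                                          (d1 + d2) / 365.25))
  expect_equal(propagate_latent_size(412, 700, k, mids[1]), 412)
})

test_that("latent-input specification finds unmeasured and unknown-sex", {
  ind <- data.frame(
    id = sprintf("x%02d", 1:12),
    sex = c(rep("female", 5), rep("male", 5), "unknown", "unknown"),
    site = "C",
    first_capture_date = as.Date("2015-05-01") + 1:12,
    first_svl_mm = c(400, 420, NA, 380, 440, 500, NA, 480, 510, 490,
                    NA, 450),
    stringsAsFactors = FALSE)
  lat <- impute_missing_inputs(ind)
  expect_equal(nrow(lat$latent_svl), 3)
  expect_equal(lat$latent_sex, c("x11", "x12"))
  f_meas <- c(400, 420, 380, 440)
  expect_equal(lat$latent_svl$prior_mean[lat$latent_svl$id == "x03"],
               mean(f_meas))
  expect_equal(lat$latent_svl$prior_sd[lat$latent_svl$id == "x03"],
               sd(f_meas))
  # unknown-sex unmeasured individuals fall back to the pooled statistics
  pooled <- ind$first_svl_mm[!is.na(ind$first_svl_mm)]
  expect_equal(lat$latent_svl$prior_mean[lat$latent_svl$id == "x11"],
               mean(pooled))
  bad <- ind[ind$sex == "female", ]
  bad$first_svl_mm <- NA
  expect_error(impute_missing_inputs(bad), "cannot build")
})

test_that("the vectorized C++ likelihood equals the per-history forward", {
  ds <- tiny_cmr_dataset(seed = 88)
  dat <- vbcmr:::cmr_model_data(ds)
  set.seed(10)
  st <- vbcmr:::cmr_init_state(dat, cmr_priors(), NULL)
  cache <- vbcmr:::cmr_cache_full(st, dat)
  for (i in seq_len(dat$N)) {
    s <- dat$site_i[i]; f <- dat$first[i]; l <- dat$last[i]
    det <- list(); pp <- list()
    for (t in f:l) {
      og <- dat$occ_off[s, t]; len <- dat$occ_len[s, t]
      lb <- og - dat$site_base[s]
      det[[t - f + 1]] <- dat$y[dat$y_off[i] + lb + seq_len(len)]
      pp[[t - f + 1]] <- plogis(cache$cmat[i, t] + cache$u[og + seq_len(len)])
    }
    ll_ref <- history_log_likelihood(
      det, pp, phi = cache$phi[i, f:(l - 1)],
      gamma = cache$gamma[i, (f + 1):l])
    expect_equal(cache$llvec[i], ll_ref, tolerance = 1e-12)
  }
})
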