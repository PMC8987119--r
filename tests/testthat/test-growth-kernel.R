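test_that("growth kernel has its fixed point, identity and bounds", {
  expect_equal(vb_expected_length(700, a = 700, k = 300, delta_years = 3),
               700)
  expect_equal(vb_expected_length(400, a = 700, k = 300, delta_years = 0),
               400)
  # direct scalar evaluation at typical posterior-mean parameters
  expect_equal(vb_expected_length(165, a = 737.23, k = exp(5.55),
                                  delta_years = 1),
               333.5524, tolerance = 1e-4)
  # strictly between previous length and asymptote; monotone in time and k
  set.seed(1)
  for (i in 1:200) {
    l0 <- runif(1, 100, 600); a <- runif(1, 620, 900)
    k <- runif(1, 10, 500); dt <- runif(1, 0.01, 10)
    v <- vb_expected_length(l0, a, k, dt)
    expect_gt(v, l0); expect_lt(v, a)
    expect_gt(vb_expected_length(l0, a, k, dt * 1.5), v)
    expect_gt(vb_expected_length(l0, a, k * 1.5, dt), v)
  }
  expect_error(vb_expected_length(100, a = -5, k = 10, delta_years = 1),
               "positive")
})

test_that("segment composition matches the closed form and is additive", {
  expect_equal(vb_compose_segments(300, 700, numeric(0), numeric(0)), 300)
  one <- vb_compose_segments(300, 700, 200, 1)
  two <- vb_compose_segments(300, 700, c(200, 200), c(0.5, 0.5))
  expect_equal(one, two, tolerance = 1e-12)
  # mixed rates collapse to the summed exponent
  mixed <- vb_compose_segments(300, 700, c(100, 300), c(0.5, 0.5))
  expect_equal(mixed, 700 - (700 - 300) * exp(-200 / 700),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:500) {
    l0 <- runif(1, 100, 600); a <- runif(1, 620, 900)
    n <- sample(1:5, 1)
    k <- runif(n, 10, 400); dt <- runif(n, 0.05, 2)
    expect_equal(vb_compose_segments(l0, a, k, dt),
                 a - (a - l0) * exp(-sum(k * dt) / a), tolerance = 1e-12)
  }
  expect_error(vb_compose_segments(300, 700, c(100, 200), c(1, -0.1)),
               "non-negative")
})

test_that("linear predictors follow the sex/site/year/individual structure", {
  pars <- list(upsilon_f = 737.23, theta_m = -186.57, mu_f = 5.55,
               beta_m = 0.34)
  f <- growth_linear_predictors(0, pars)
  expect_equal(f$a, 737.23)
  expect_equal(f$log_k, 5.55)
  m <- growth_linear_predictors(1, pars)
  expect_equal(m$a, 550.66, tolerance = 1e-9)
  expect_equal(m$log_k, 5.89)
  full <- growth_linear_predictors(1, pars, eta = 10, alpha = 0.2,
                                   zeta = c(-0.1, 0.1), iota = 0.05)
  expect_equal(full$a, 560.66, tolerance = 1e-9)
  expect_equal(full$log_k, 5.89 + 0.2 + c(-0.1, 0.1) + 0.05)
})

test_that("increments split at calendar-year boundaries", {
  seg <- vbcmr:::increment_year_segments(as.Date("2007-05-01"),
                                         as.Date("2008-09-20"))
  expect_equal(seg$year, c(2007, 2008))
  expect_equal(sum(seg$dt_years) * 365.25, 508, tolerance = 1e-9)
  within <- vbcmr:::increment_year_segments(as.Date("2010-04-01"),
                                            as.Date("2010-06-01"))
  expect_equal(nrow(within), 1)
})

test_that("growth log-likelihood matches a term-by-term oracle", {
  inc <- make_events(
    rep(c("a", "b", "c"), each = 2), "C",
    c("2010-05-01", "2011-05-01", "2010-05-10", "2012-05-10",
      "2010-04-20", "2011-08-01"),
    rep(c("female", "male", "female"), each = 2),
    c(300, 390, 400, 520, 250, 360))
  incs <- build_growth_increments(inc)
  pars <- list(upsilon_f = 737.23, theta_m = -186.57, mu_f = 5.55,
               beta_m = 0.34, sigma_e = 23.33)
  ll <- growth_log_likelihood(incs, pars)
  # oracle: independent scalar computation per increment
  oracle <- 0
  for (j in seq_len(nrow(incs))) {
    male <- as.numeric(incs$sex[j] == "male")
    a <- 737.23 - 186.57 * male
    k <- exp(5.55 + 0.34 * male)
    dt <- incs$delta_days[j] / 365.25
    mu <- a - (a - incs$l_start_mm[j]) * exp(-k * dt / a)
    oracle <- oracle + dnorm(incs$l_end_mm[j], mu, 23.33, log = TRUE)
  }
  expect_equal(as.numeric(ll), oracle, tolerance = 1e-10)
  # normal-density anchors
  one <- incs[1, ]
  mu1 <- 737.23 - (737.23 - 300) * exp(-exp(5.55) * (365 / 365.25) / 737.23)
  one$l_end_mm <- mu1
  at_mode <- growth_log_likelihood(one, pars)
  expect_equal(as.numeric(at_mode), -log(23.33 * sqrt(2 * pi)),
               tolerance = 1e-10)
  pars2 <- pars; pars2$sigma_e <- 2 * pars$sigma_e
  expect_equal(as.numeric(at_mode) - as.numeric(
    growth_log_likelihood(one, pars2)), log(2), tolerance = 1e-10)
  pars_bad <- pars; pars_bad$sigma_e <- 0
  expect_error(growth_log_likelihood(one, pars_bad), "positive")
})
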