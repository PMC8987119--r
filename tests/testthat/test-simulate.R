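test_that("simulation is seed-reproducible end to end", {
  cfg <- simulation_config(
    n_years = c(C = 3, I = 2), start_year = c(C = 2012, I = 2013),
    occasions_per_year = 6L, n_individuals = c(C = 60, I = 40))
  a <- simulate_study(cfg, seed = 5)
  b <- simulate_study(cfg, seed = 5)
  expect_equal(a$dataset$events, b$dataset$events)
  expect_equal(a$truth$svl_true, b$truth$svl_true)
  c <- simulate_study(cfg, seed = 6)
  expect_false(identical(a$dataset$events, c$dataset$events))
  # byte-identical files from the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, seed = 5, dir = d1)
  simulate_study(cfg, seed = 5, dir = d2)
  for (f in c("captures.csv", "surveys.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("rosters follow the configured sex ratio and missingness", {
  cfg <- simulation_config(
    n_years = c(C = 3, I = 2), start_year = c(C = 2012, I = 2013),
    occasions_per_year = 6L, n_individuals = c(C = 7000, I = 3000))
  ind <- simulate_individuals(cfg, seed = 31)
  n <- nrow(ind)
  frac_m <- mean(ind$sex_true == "male")
  # binomial 99.9% interval at n = 10,000
  expect_lt(abs(frac_m - 0.5), 3.3 * sqrt(0.25 / n))
  frac_unk <- mean(ind$sex_recorded == "unknown")
  expect_lt(abs(frac_unk - cfg$missing$unknown_sex),
            3.3 * sqrt(0.034 * 0.966 / n))
  cfg0 <- simulation_config(
    n_years = c(C = 3, I = 2), start_year = c(C = 2012, I = 2013),
    occasions_per_year = 6L, n_individuals = c(C = 500, I = 100),
    missing = list(unmeasured_first = 0, unmeasured_recapture = 0,
                   unknown_sex = 0))
  ind0 <- simulate_individuals(cfg0, seed = 32)
  expect_true(all(ind0$sex_recorded != "unknown"))
})

test_that("growth trajectories respect the asymptote and noise level", {
  cfg <- simulation_config(
    n_years = c(C = 4, I = 3), start_year = c(C = 2011, I = 2012),
    occasions_per_year = 8L, n_individuals = c(C = 1200, I = 800))
  gd <- simulate_remeasurement_events(cfg, seed = 41)
  gr <- gd$truth$growth
  ind <- gd$truth$individuals
  # true lengths never exceed the individual asymptote
  expect_true(all(gr$svl <= gr$a + 1e-9, na.rm = TRUE))
  # measurement noise at first capture: observed - true has mean ~0 and
  # SD ~ sigma_e (later measurements carry propagated deviations by the
  # model's Markov structure)
  ev <- gd$events
  first <- ev[!duplicated(ev$individual_id), ]
  true_at <- mapply(function(id, d) {
    gr$svl[id, as.character(as.integer(format(d, "%Y")))]
  }, first$individual_id, first$date)
  resid <- first$svl_mm - true_at
  n <- length(resid)
  expect_gt(n, 1200)
  expect_lt(abs(mean(resid)), 4 * cfg$growth$sigma_e / sqrt(n))
  expect_lt(abs(sd(resid) - cfg$growth$sigma_e), 2)
  # degenerate hierarchy: all females follow one deterministic trajectory
  cfg0 <- simulation_config(
    n_years = c(C = 3, I = 2), start_year = c(C = 2012, I = 2013),
    occasions_per_year = 6L, n_individuals = c(C = 40, I = 20),
    growth = list(sigma_k_year = 0, sigma_k_site = 0, sigma_k_indiv = 0,
                  sigma_a_site = 0, l0_sd = 0))
  ind0 <- simulate_individuals(cfg0, seed = 42)
  gr0 <- simulate_growth(ind0, cfg0, seed = 43)
  fem <- ind0$sex_true == "female" & ind0$birth_year == ind0$birth_year[1]
  if (sum(fem) > 1) {
    traj <- gr0$svl[fem, , drop = FALSE]
    for (col in seq_len(ncol(traj))) {
      v <- traj[, col][!is.na(traj[, col])]
      if (length(v) > 1) expect_lt(diff(range(v)), 1e-9)
    }
  }
})

test_that("surveys match the configured design and generators", {
  cfg <- simulation_config(
    n_years = c(C = 3, I = 2), start_year = c(C = 2012, I = 2013),
    occasions_per_year = 52L, n_individuals = c(C = 40, I = 20))
  occ <- simulate_surveys(cfg, seed = 51)
  counts <- table(occ$site, occ$year)
  expect_true(all(counts[counts > 0] == 52))
  n <- nrow(occ)
  expect_lt(abs(mean(occ$air_temp_c) - cfg$covariates$temp_mean),
            3 * cfg$covariates$temp_sd / sqrt(n))
  cfg_dry <- simulation_config(
    n_years = c(C = 3, I = 2), start_year = c(C = 2012, I = 2013),
    occasions_per_year = 10L, n_individuals = c(C = 40, I = 20),
    covariates = list(precip_prob = 0))
  expect_true(all(simulate_surveys(cfg_dry, seed = 52)$precip_24h == 0))
})

test_that("detections only occur while available, and conditioning holds", {
  cfg <- simulation_config(
    n_years = c(C = 4, I = 3), start_year = c(C = 2011, I = 2012),
    occasions_per_year = 12L, n_individuals = c(C = 300, I = 150))
  sim <- simulate_study(cfg, seed = 61)
  ds <- sim$dataset
  tr <- sim$truth
  # every capture event happens in a year the individual was available
  yr <- as.integer(format(ds$events$date, "%Y"))
  ok <- mapply(function(id, y) tr$available[id, as.character(y)],
               ds$events$individual_id, yr)
  expect_true(all(ok))
  # dataset contains only detected individuals
  expect_true(all(ds$individuals$id %in% ds$events$individual_id))
  # realized annual survival tracks the configured rates; site C spans the
  # full year range, so its alive -> alive-next-year transitions are clean
  alive <- tr$alive[grepl("^C", rownames(tr$alive)), , drop = FALSE]
  n_trans <- surv <- 0
  for (i in seq_len(nrow(alive))) {
    idx <- which(alive[i, ])
    if (length(idx) == 0 || min(idx) >= ncol(alive)) next
    for (t in seq(min(idx), ncol(alive) - 1)) {
      if (alive[i, t]) {
        n_trans <- n_trans + 1
        surv <- surv + alive[i, t + 1]
      }
    }
  }
  frac <- surv / n_trans
  expect_gt(frac, 0.3); expect_lt(frac, 0.85)
})

test_that("study-scale defaults give study-like recapture structure", {
  sim <- simulate_study(simulation_config(), seed = 7)
  s <- summarize_dataset(sim$dataset)
  ov <- s[s$site == "overall", ]
  recap_later <- 1 - ov$years_1 / ov$individuals
  expect_gt(recap_later, 0.10)
  expect_lt(recap_later, 0.30)
})
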