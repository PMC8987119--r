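# Generative emulation of a multi-year robust-design CMR study on a
# long-lived, hard-to-detect snake: individuals recruit in a staggered way,
# grow along von Bertalanffy trajectories with hierarchical variation,
# move in and out of availability, and are detected daily during a spring
# survey window.  Everything is simulated from the same model equations the
# fitting functions use, so truth records support parameter-recovery tests.

#' Configuration of the study simulator
#'
#' Defaults emulate a two-site study: one long site (14 annual primary
#' periods) and one short site (4), ~52 daily secondary occasions per year,
#' and demographic truth set to typical posterior values for an endangered
#' gartersnake: female asymptote 737 mm with a -187 mm male effect, log
#' growth coefficient 5.55 (+0.34 for males), annual survival 0.52-0.68,
#' availability 0.33-0.65, and daily capture probability 0.010-0.020,
#' varying by sex and site.  Size effects on the logit scale are anchored at
#' the reference SVL (463 mm): survival is flat up to 550 mm then declines,
#' capture probability rises to a plateau at 500 mm, availability increases
#' linearly.  Slopes are expressed per 100 mm of SVL; survey-covariate
#' effects are per SD of the covariate generator.
#'
#' @param ... named overrides of any top-level default.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    sites = c("C", "I"),
    start_year = c(C = 2007, I = 2014),
    n_years = c(C = 14, I = 4),
    occasions_per_year = 52L,
    n_individuals = c(C = 900, I = 250),
    sex_ratio = 0.5,
    neonate_fraction = 0.3,
    max_entry_age = 8L,
    growth = list(upsilon_f = 737.23, theta_m = -186.57, mu_f = 5.55,
                  beta_m = 0.34, sigma_k_year = 0.14, sigma_k_site = 0.56,
                  sigma_k_indiv = 0.42, sigma_a_site = 25.70,
                  sigma_e = 23.33, l0_mean = 165, l0_sd = 10),
    cmr = list(
      p_mean = c(female.C = 0.010, male.C = 0.010,
                 female.I = 0.014, male.I = 0.020),
      phi_mean = c(female.C = 0.660, male.C = 0.521,
                   female.I = 0.523, male.I = 0.677),
      gamma_mean = c(female.C = 0.330, male.C = 0.651,
                     female.I = 0.633, male.I = 0.594),
      delta = c(air_temp = 0.183, rel_humidity = -0.214,
                day_of_year = -0.265, precip = -0.652),
      sigma_p_year = 0.647, sigma_phi_year = 1.186,
      sigma_gamma_year = 1.359, rho_k_phi = 0.012,
      lambda_gamma = 0.5  # logit availability per 100 mm SVL
    ),
    size_effects = list(
      reference_svl = 463,
      survival = list(type = "piecewise", flat_until = 550,
                      drop_per_100mm = 1.0, upper = 700),
      capture = list(type = "ramp", rise_per_100mm = 0.8, plateau_at = 500)
    ),
    covariates = list(temp_mean = 15, temp_sd = 3.5, rh_mean = 75,
                      rh_sd = 10, precip_prob = 0.2, start_doy = 91L),
    missing = list(unmeasured_first = 0.011, unmeasured_recapture = 0.01,
                   unknown_sex = 0.034)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  stop_if(length(unknown) > 0, "unknown simulation setting(s): ",
          paste(unknown, collapse = ", "))
  for (nm in names(override)) {
    if (is.list(cfg[[nm]]) && is.list(override[[nm]])) {
      cfg[[nm]][names(override[[nm]])] <- override[[nm]]
    } else {
      cfg[[nm]] <- override[[nm]]
    }
  }
  stop_if(cfg$occasions_per_year < 1L, "need at least one occasion per year")
  stop_if(any(cfg$n_years < 2L), "each site needs at least two years")
  probs <- c(cfg$cmr$p_mean, cfg$cmr$phi_mean, cfg$cmr$gamma_mean,
             cfg$sex_ratio, cfg$neonate_fraction,
             unlist(cfg$missing), cfg$covariates$precip_prob)
  stop_if(any(probs < 0 | probs > 1), "probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# truth size effects on the logit scale, anchored at the reference SVL
sim_size_effect <- function(svl, eff, ref) {
  if (is.null(eff) || eff$type == "none") return(rep(0, length(svl)))
  if (eff$type == "piecewise") {
    -eff$drop_per_100mm *
      (pmin(pmax(svl, eff$flat_until), eff$upper) - eff$flat_until) / 100
  } else if (eff$type == "ramp") {
    eff$rise_per_100mm * (pmin(svl, eff$plateau_at) -
                            pmin(ref, eff$plateau_at)) / 100
  } else if (eff$type == "linear") {
    eff$slope_per_100mm * (svl - ref) / 100
  } else stop("unknown size-effect type '", eff$type, "'")
}

#' Simulate survey occasions
#'
#' Daily occasions within a spring window starting at `start_doy`, with
#' air temperature and relative humidity from normal generators and a
#' Bernoulli precipitation flag.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return survey occasion data frame (same schema as [read_surveys()]).
#' @export
simulate_surveys <- function(config, seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  cv <- config$covariates
  rows <- list()
  for (s in config$sites) {
    years <- seq(config$start_year[[s]],
                 length.out = config$n_years[[s]])
    for (y in years) {
      d0 <- as.Date(paste0(y, "-01-01")) + (cv$start_doy - 1L)
      dates <- d0 + seq_len(config$occasions_per_year) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, date = dates,
        air_temp_c = round(rnorm(length(dates), cv$temp_mean, cv$temp_sd),
                           1),
        rel_humidity_pct = round(pmin(pmax(
          rnorm(length(dates), cv$rh_mean, cv$rh_sd), 5), 100), 1),
        precip_24h = rbinom(length(dates), 1, cv$precip_prob),
        stringsAsFactors = FALSE
      )
    }
  }
  occ <- do.call(rbind, rows)
  occ$year <- as.integer(format(occ$date, "%Y"))
  occ$day_of_year <- as.integer(format(occ$date, "%j"))
  occ$primary_index <- NA_integer_
  occ$secondary_index <- NA_integer_
  for (s in unique(occ$site)) {
    sel <- occ$site == s
    occ$primary_index[sel] <- match(occ$year[sel],
                                    sort(unique(occ$year[sel])))
    for (t in unique(occ$primary_index[sel])) {
      sel2 <- sel & occ$primary_index == t
      occ$secondary_index[sel2] <- rank(occ$date[sel2])
    }
  }
  occ
}

#' Simulate the individual roster
#'
#' Individuals are assigned a site, a true sex (Bernoulli 1/2), a staggered
#' entry year (uniform over the site's sampling years), and an age at entry:
#' neonates (age 0, born the previous autumn) with the configured
#' probability, otherwise a uniform age between 1 and `max_entry_age`.
#' Unknown-sex labels are applied after the true sex is recorded.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return data frame of individuals with truth columns.
#' @export
simulate_individuals <- function(config, seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rows <- list()
  for (s in config$sites) {
    n <- config$n_individuals[[s]]
    years <- seq(config$start_year[[s]], length.out = config$n_years[[s]])
    age <- ifelse(runif(n) < config$neonate_fraction, 0L,
                  sample.int(config$max_entry_age, n, replace = TRUE))
    entry <- sample(years, n, replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%s%04d", s, seq_len(n)),
      site = s,
      sex_true = ifelse(runif(n) < config$sex_ratio, "male", "female"),
      entry_year = entry,
      age_at_entry = age,
      birth_year = entry - 1L - age,
      stringsAsFactors = FALSE
    )
  }
  ind <- do.call(rbind, rows)
  ind$sex_recorded <- ifelse(runif(nrow(ind)) < config$missing$unknown_sex,
                             "unknown", ind$sex_true)
  ind
}

#' Simulate true growth trajectories
#'
#' Draws the hierarchical growth effects (sex-site effects on asymptote and
#' log growth coefficient, year and individual effects on log k, neonate
#' length N(l0_mean, l0_sd)) and composes the von Bertalanffy kernel year by
#' year from birth (1 September of the birth year) to each survey-season
#' midpoint.  Lengths never exceed the individual's asymptote.
#'
#' @param individuals from [simulate_individuals()].
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param xi_year optional pre-drawn survival year effects (named by year)
#'   so that growth year effects can be drawn jointly with them (correlation
#'   `rho_k_phi`); drawn here when NULL.
#' @return list with `svl` (individuals by survey years matrix of true SVL
#'   at the season midpoint, NA before entry), `effects` (all drawn random
#'   effects), `a` and `log_k_base` per individual.
#' @export
simulate_growth <- function(individuals, config, seed = 1L,
                            xi_year = NULL) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  g <- config$growth
  survey_years <- sort(unique(unlist(lapply(config$sites, function(s) {
    seq(config$start_year[[s]], length.out = config$n_years[[s]])
  }))))
  all_years <- seq(min(individuals$birth_year), max(survey_years))
  ss_levels <- as.vector(outer(c("female", "male"), config$sites, paste,
                               sep = "."))
  eta <- setNames(rnorm(length(ss_levels), 0, g$sigma_a_site), ss_levels)
  alpha <- setNames(rnorm(length(ss_levels), 0, g$sigma_k_site), ss_levels)
  # year effects: bivariate with the survival year effects over survey
  # years, independent before the study
  rho <- config$cmr$rho_k_phi
  if (is.null(xi_year)) {
    xi_year <- setNames(rnorm(length(survey_years), 0,
                              config$cmr$sigma_phi_year),
                        survey_years)
  }
  zeta <- setNames(rnorm(length(all_years), 0, g$sigma_k_year), all_years)
  in_study <- as.character(survey_years)
  zeta[in_study] <- rho * (g$sigma_k_year / config$cmr$sigma_phi_year) *
    xi_year[in_study] +
    sqrt(1 - rho^2) * rnorm(length(in_study), 0, g$sigma_k_year)
  iota <- rnorm(nrow(individuals), 0, g$sigma_k_indiv)
  l0 <- rnorm(nrow(individuals), g$l0_mean, g$l0_sd)

  m <- as.numeric(individuals$sex_true == "male")
  ss <- paste(individuals$sex_true, individuals$site, sep = ".")
  a <- g$upsilon_f + g$theta_m * m + eta[ss]
  stop_if(any(a <= 0), "simulated asymptote non-positive; check config")
  log_k_base <- g$mu_f + g$beta_m * m + alpha[ss] + iota

  # season midpoint: start_doy + half the window
  mid_doy <- config$covariates$start_doy + config$occasions_per_year / 2
  svl <- matrix(NA_real_, nrow(individuals), length(survey_years),
                dimnames = list(individuals$id, survey_years))
  for (i in seq_len(nrow(individuals))) {
    born <- individuals$birth_year[i]
    # grow from birth (1 Sep, day 244) through successive year midpoints
    len <- l0[i]
    # first survey-season midpoint after birth is in year born + 1
    prev_time <- born + 244 / 365
    for (y in seq(born + 1L, max(survey_years))) {
      t_mid <- y + mid_doy / 365
      k <- exp(log_k_base[i] + zeta[as.character(y)] %||% 0)
      if (is.na(k)) k <- exp(log_k_base[i])
      len <- vb_expected_length(len, a[i], k, t_mid - prev_time)
      prev_time <- t_mid
      if (y %in% survey_years && y >= individuals$entry_year[i]) {
        svl[i, as.character(y)] <- len
      }
    }
  }
  list(svl = svl, a = a, log_k_base = log_k_base,
       effects = list(eta = eta, alpha = alpha, zeta = zeta,
                      xi = xi_year, iota = iota, l0 = l0),
       survey_years = survey_years)
}

#' Simulate latent states, detections, and the capture dataset
#'
#' From each individual's entry year, survival and availability evolve by
#' the three-state random-emigration transition structure; detections are
#' daily Bernoulli trials with the occasion's capture probability while
#' available.  Only individuals detected at least once enter the returned
#' dataset (CJS conditioning), and each detection becomes a capture event
#' with a noisy SVL measurement (missing at configured rates).
#'
#' @param individuals from [simulate_individuals()].
#' @param growth from [simulate_growth()].
#' @param surveys from [simulate_surveys()].
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `dataset` (a [capture_dataset()]), and `truth` (latent
#'   states, true sizes, all parameters and effects).
#' @export
simulate_states_and_detections <- function(individuals, growth, surveys,
                                           config, seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  cm <- config$cmr
  se <- config$size_effects
  ref <- se$reference_svl
  years <- growth$survey_years
  xi <- growth$effects$xi

  # site-year random effects on capture and availability
  omega <- nu <- list()
  for (s in config$sites) {
    ys <- seq(config$start_year[[s]], length.out = config$n_years[[s]])
    omega[[s]] <- setNames(rnorm(length(ys), 0, cm$sigma_p_year), ys)
    nu[[s]] <- setNames(rnorm(length(ys), 0, cm$sigma_gamma_year), ys)
  }

  cv <- config$covariates
  W <- cbind(air_temp = (surveys$air_temp_c - cv$temp_mean) / cv$temp_sd,
             rel_humidity = (surveys$rel_humidity_pct - cv$rh_mean) /
               cv$rh_sd,
             day_of_year = (surveys$day_of_year -
                              (cv$start_doy + config$occasions_per_year /
                                 2)) / (config$occasions_per_year / 3.5),
             precip = surveys$precip_24h)
  u_occ <- drop(W %*% cm$delta) +
    mapply(function(s, y) omega[[s]][as.character(y)],
           surveys$site, surveys$year)

  N <- nrow(individuals)
  Ty <- length(years)
  alive <- avail <- matrix(FALSE, N, Ty, dimnames = list(individuals$id,
                                                         years))
  ss <- paste(individuals$sex_true, individuals$site, sep = ".")
  events <- list()
  for (i in seq_len(N)) {
    s <- individuals$site[i]
    site_years <- seq(config$start_year[[s]],
                      length.out = config$n_years[[s]])
    active <- site_years[site_years >= individuals$entry_year[i]]
    if (!length(active)) next
    is_alive <- TRUE
    for (y in active) {
      t <- match(y, years)
      if (y == active[1]) {
        is_avail <- TRUE  # recruitment: on-site in the entry year
      } else {
        svl_prev <- growth$svl[i, as.character(y - 1L)]
        phi <- plogis(qlogis(cm$phi_mean[[ss[i]]]) +
                        sim_size_effect(svl_prev, se$survival, ref) +
                        xi[as.character(y - 1L)])
        is_alive <- is_alive && (runif(1) < phi)
        svl_now <- growth$svl[i, as.character(y)]
        gam <- plogis(qlogis(cm$gamma_mean[[ss[i]]]) +
                        cm$lambda_gamma * (svl_now - ref) / 100 +
                        nu[[s]][as.character(y)])
        is_avail <- is_alive && (runif(1) < gam)
      }
      alive[i, t] <- is_alive
      avail[i, t] <- is_avail
      if (!is_avail) next
      occ_rows <- which(surveys$site == s & surveys$year == y)
      svl_now <- growth$svl[i, as.character(y)]
      logit_p <- qlogis(cm$p_mean[[ss[i]]]) +
        sim_size_effect(svl_now, se$capture, ref) + u_occ[occ_rows]
      det <- runif(length(occ_rows)) < plogis(logit_p)
      if (any(det)) {
        events[[length(events) + 1L]] <- data.frame(
          individual_id = individuals$id[i],
          site = s,
          date = surveys$date[occ_rows[det]],
          svl_true = svl_now,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  stop_if(length(events) == 0L,
          "no detections simulated; configuration is degenerate")
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$individual_id, ev$date), , drop = FALSE]

  # measurement noise and missingness
  g <- config$growth
  ev$svl_mm <- round(ev$svl_true + rnorm(nrow(ev), 0, g$sigma_e))
  ev$svl_mm <- pmin(pmax(ev$svl_mm, 1), 999)
  first_row <- !duplicated(ev$individual_id)
  miss <- ifelse(first_row,
                 runif(nrow(ev)) < config$missing$unmeasured_first,
                 runif(nrow(ev)) < config$missing$unmeasured_recapture)
  ev$svl_mm[miss] <- NA
  ev$sex <- individuals$sex_recorded[match(ev$individual_id,
                                           individuals$id)]
  ev$mass_g <- NA_real_
  ev$svl_true <- NULL

  individuals_out <- do.call(rbind, lapply(split(ev, ev$individual_id),
    function(e) {
      data.frame(id = e$individual_id[1], sex = e$sex[1], site = e$site[1],
                 first_capture_date = e$date[1], first_svl_mm = e$svl_mm[1],
                 stringsAsFactors = FALSE)
    }))
  rownames(individuals_out) <- NULL
  ev <- ev[, c("individual_id", "site", "date", "sex", "svl_mm", "mass_g")]
  rownames(ev) <- NULL

  dataset <- capture_dataset(ev, individuals_out, surveys)
  truth <- list(
    config = unclass(config),
    individuals = individuals,
    a = growth$a, log_k_base = growth$log_k_base,
    effects = growth$effects,
    omega = omega, nu = nu,
    svl_true = growth$svl, alive = alive, available = avail
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate a growth-focused remeasurement survey
#'
#' Produces capture events for a growth analysis: every individual is
#' measured in its entry year and again in one or two later survey years
#' (three total captures with probability `p_three`).  Measurements follow
#' the growth model's own Markov structure: each remeasured length is drawn
#' from a normal distribution centered on the von Bertalanffy projection of
#' the *previous observed* length over the elapsed interval (segmented at
#' calendar-year boundaries so year effects apply to the time spent in each
#' year), with SD `sigma_e`.  The first measurement adds the same noise to
#' the individual's true length.  This emulates the dense remeasurement
#' data a growth study contributes on top of sparser CMR detections, and is
#' the generator used for growth parameter-recovery checks.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param p_three probability an individual is measured three times
#'   (default 0.1, i.e. most are measured twice).
#' @return list with `events` (capture-event data frame) and `truth`
#'   (individuals, trajectories, effects).
#' @export
simulate_remeasurement_events <- function(config, seed = 1L,
                                          p_three = 0.1) {
  base <- as.integer(seed) %% 1000000L
  individuals <- simulate_individuals(config, seed = base * 11L + 1L)
  growth <- simulate_growth(individuals, config, seed = base * 11L + 2L)
  set.seed(base * 11L + 3L)
  g <- config$growth
  zeta <- growth$effects$zeta
  rows <- list()
  for (i in seq_len(nrow(individuals))) {
    yrs <- colnames(growth$svl)[!is.na(growth$svl[i, ])]
    if (length(yrs) < 2L) next
    ncap <- if (length(yrs) >= 3L && runif(1) < p_three) 3L else 2L
    take <- sort(c(yrs[1], sample(yrs[-1], ncap - 1L)))
    dates <- as.Date(paste0(take, "-05-01")) +
      sample.int(31L, length(take), replace = TRUE) - 1L
    # first observation: true length plus measurement noise; later ones
    # follow the model's Markov chain from the previous observation
    l_obs <- round(growth$svl[i, take[1]] + rnorm(1, 0, g$sigma_e))
    svls <- l_obs
    if (length(take) > 1L) {
      for (j in 2:length(take)) {
        seg <- increment_year_segments(dates[j - 1L], dates[j])
        z <- zeta[as.character(seg$year)]
        z[is.na(z)] <- 0
        mu <- vb_compose_segments(l_obs, growth$a[i],
                                  exp(growth$log_k_base[i] + z),
                                  seg$dt_years)
        l_obs <- round(rnorm(1, mu, g$sigma_e))
        svls <- c(svls, l_obs)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = individuals$id[i], site = individuals$site[i],
      date = dates, sex = individuals$sex_recorded[i],
      svl_mm = pmin(pmax(svls, 1), 999), mass_g = NA_real_,
      stringsAsFactors = FALSE)
  }
  stop_if(length(rows) == 0L, "no remeasured individuals; config degenerate")
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$individual_id, ev$date), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, truth = list(individuals = individuals,
                                 growth = growth))
}

#' Simulate a complete study
#'
#' Runs the full generative pipeline (surveys, individuals, growth, states
#' and detections) from one seed, optionally writing `captures.csv`,
#' `surveys.csv`, `truth.json` and the echoed configuration to a directory.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; all randomness derives from it.
#' @param dir optional output directory.
#' @return list with `dataset`, `truth`, `config`.
#' @export
simulate_study <- function(config = simulation_config(), seed = 1L,
                           dir = NULL) {
  base <- as.integer(seed) %% 1000000L
  surveys <- simulate_surveys(config, seed = base * 7L + 1L)
  individuals <- simulate_individuals(config, seed = base * 7L + 2L)
  growth <- simulate_growth(individuals, config, seed = base * 7L + 3L)
  out <- simulate_states_and_detections(individuals, growth, surveys,
                                        config, seed = base * 7L + 4L)
  out$config <- config
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_captures(out$dataset$events, file.path(dir, "captures.csv"))
    write_surveys(out$dataset$surveys, file.path(dir, "surveys.csv"))
    truth <- out$truth
    truth$svl_true <- as.data.frame(truth$svl_true)
    truth$alive <- as.data.frame(truth$alive)
    truth$available <- as.data.frame(truth$available)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
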