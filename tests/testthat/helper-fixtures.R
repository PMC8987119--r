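# Shared fixture builders and independent oracles, all generated in code.

# capture events table from a compact spec
make_events <- function(ids, sites, dates, sexes, svls, masses = NA) {
  data.frame(individual_id = ids, site = sites, date = as.Date(dates),
             sex = sexes, svl_mm = svls,
             mass_g = rep_len(masses, length(ids)),
             stringsAsFactors = FALSE)
}

make_individuals <- function(events) {
  do.call(rbind, lapply(split(events, events$individual_id), function(ev) {
    ev <- ev[order(ev$date), ]
    sexes <- setdiff(unique(ev$sex), "unknown")
    data.frame(id = ev$individual_id[1],
               sex = if (length(sexes) == 1) sexes else "unknown",
               site = ev$site[1], first_capture_date = ev$date[1],
               first_svl_mm = ev$svl_mm[1], stringsAsFactors = FALSE)
  }))
}

# minimal complete surveys table covering given (site, date) pairs
make_surveys_for <- function(events, extra_dates = NULL) {
  sd <- unique(rbind(events[c("site", "date")], extra_dates))
  occ <- data.frame(site = sd$site, date = as.Date(sd$date),
                    air_temp_c = 15, rel_humidity_pct = 70,
                    precip_24h = 0L, stringsAsFactors = FALSE)
  occ <- occ[order(occ$site, occ$date), ]
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
  rownames(occ) <- NULL
  occ
}

# brute-force enumeration over all latent-state sequences; independent of
# the forward algorithm
enum_history_ll <- function(detections, p, phi, gamma) {
  Tn <- length(detections)
  first_det <- which(detections[[1]] == 1)[1]
  keep <- seq_along(detections[[1]]) > first_det
  e1 <- emission_probability("available", detections[[1]][keep],
                             p[[1]][keep])
  if (Tn == 1) return(log(e1))
  states <- c("available", "unavailable", "dead")
  grids <- do.call(expand.grid, rep(list(1:3), Tn - 1))
  tot <- 0
  for (r in seq_len(nrow(grids))) {
    path <- c(1, as.integer(grids[r, ]))
    pr <- e1
    for (t in 2:Tn) {
      tm <- transition_matrix(phi[t - 1], gamma[t - 1])
      pr <- pr * tm[path[t - 1], path[t]] *
        emission_probability(states[path[t]], detections[[t]], p[[t]])
    }
    tot <- tot + pr
  }
  log(tot)
}

# classic CJS likelihood (single detection per primary), hand-coded:
# condition on release, survival phi per interval, detection prob pstar
cjs_ll <- function(det, phi, pstar) {
  Tn <- length(det)
  chi <- 1  # probability of never being seen again, computed backwards
  ll <- 0
  last_seen <- max(which(det == 1))
  if (last_seen > 1) {
    for (t in 2:last_seen) {
      ll <- ll + log(phi[t - 1]) +
        ifelse(det[t] == 1, log(pstar[t]), log(1 - pstar[t]))
    }
  }
  # probability of the all-zero tail after the last detection
  chi <- 1
  if (last_seen < Tn) {
    for (t in Tn:(last_seen + 1)) {
      chi <- 1 - phi[t - 1] + phi[t - 1] * (1 - pstar[t]) * chi
    }
  }
  ll + log(chi)
}

# small simulated growth-increment set at the default truth
small_growth_increments <- function(seed = 77, n_c = 40, n_i = 25) {
  cfg <- simulation_config(
    n_years = c(C = 5, I = 4), start_year = c(C = 2010, I = 2011),
    occasions_per_year = 10L, n_individuals = c(C = n_c, I = n_i))
  gd <- simulate_remeasurement_events(cfg, seed = seed)
  suppressWarnings(build_growth_increments(gd$events))
}

# a tiny CMR dataset that fits in seconds
tiny_cmr_dataset <- function(seed = 88) {
  cfg <- simulation_config(
    n_years = c(C = 4, I = 3), start_year = c(C = 2011, I = 2012),
    occasions_per_year = 10L, n_individuals = c(C = 120, I = 70))
  sim <- simulate_study(cfg, seed = seed)
  filter_cmr_individuals(sim$dataset)
}

# deterministic fake posterior for derived-quantity tests: a vb_cmr_fit-like
# object with hand-chosen draws
fake_cmr_fit <- function(n_draws = 50, seed = 3) {
  set.seed(seed)
  svl <- runif(200, 250, 700)
  spec <- spline_spec(svl, n_knots = 5, degree = 3)
  labs <- c("pi_phi[female.C]", "o_p[female.C]", "zeta_gamma[female.C]",
            "lambda_gamma", "q_phi", paste0("b_phi[", 1:5, "]"),
            "q_p", paste0("b_p[", 1:5, "]"))
  m <- matrix(0, n_draws, length(labs), dimnames = list(NULL, labs))
  m[, "pi_phi[female.C]"] <- rnorm(n_draws, 0.5, 0.2)
  m[, "o_p[female.C]"] <- rnorm(n_draws, -4, 0.2)
  m[, "zeta_gamma[female.C]"] <- rnorm(n_draws, -0.5, 0.2)
  m[, "lambda_gamma"] <- runif(n_draws, 0.2, 0.8)  # strictly positive
  m[, "q_phi"] <- rnorm(n_draws, 0.3, 0.1)
  structure(list(draws = posterior_draws(list(m)), spline_spec = spec,
                 sex_site_levels = "female.C"),
            class = "vb_cmr_fit")
}
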