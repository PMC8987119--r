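# Joint three-state robust-design CJS model with an embedded von
# Bertalanffy growth block: data preparation, cached likelihood evaluation
# (R linear predictors + C++ forward algorithm), adaptive
# Metropolis-within-Gibbs sampler, and posterior-predictive support.

# ---------------------------------------------------------------------------
# data preparation

cmr_model_data <- function(dataset, n_knots = 5L, degree = 3L,
                           reference_svl = 463) {
  ind <- dataset$individuals
  stop_if(nrow(ind) == 0, "empty CMR dataset")
  sites <- sort(unique(ind$site))
  occ <- dataset$surveys[dataset$surveys$site %in% sites, , drop = FALSE]
  stop_if(nrow(occ) == 0, "no survey occasions for the CMR sites")
  years <- sort(unique(occ$year))
  Ty <- length(years)
  S <- length(sites)
  for (s in sites) {
    ys <- sort(unique(occ$year[occ$site == s]))
    stop_if(any(diff(ys) != 1L), "site '", s,
            "' has non-consecutive survey years")
  }
  occ$gsite <- match(occ$site, sites)
  occ$gyear <- match(occ$year, years)
  occ <- occ[order(occ$gsite, occ$gyear, occ$date), , drop = FALSE]
  n_occ <- nrow(occ)

  occ_off <- matrix(-1L, S, Ty)
  occ_len <- matrix(0L, S, Ty)
  for (r in seq_len(n_occ)) {
    s <- occ$gsite[r]; t <- occ$gyear[r]
    if (occ_off[s, t] < 0L) occ_off[s, t] <- r - 1L
    occ_len[s, t] <- occ_len[s, t] + 1L
  }
  site_base <- vapply(seq_len(S), function(s) {
    min(which(occ$gsite == s)) - 1L
  }, integer(1))
  occ_sy <- matrix(NA_integer_, S, Ty)  # site-year cell index
  sy_cells <- which(occ_len > 0L, arr.ind = TRUE)
  sy_cells <- sy_cells[order(sy_cells[, 1], sy_cells[, 2]), , drop = FALSE]
  occ_sy[sy_cells] <- seq_len(nrow(sy_cells))
  sy_labels <- paste(sites[sy_cells[, 1]], years[sy_cells[, 2]], sep = ".")

  std <- list(air_temp = standardizer(occ$air_temp_c),
              rel_humidity = standardizer(occ$rel_humidity_pct),
              day_of_year = standardizer(occ$day_of_year))
  W <- cbind(air_temp = std_apply(occ$air_temp_c, std$air_temp),
             rel_humidity = std_apply(occ$rel_humidity_pct,
                                      std$rel_humidity),
             day_of_year = std_apply(occ$day_of_year, std$day_of_year),
             precip = occ$precip_24h)
  occ_sy_idx <- occ_sy[cbind(occ$gsite, occ$gyear)]

  # midpoints of each site-year survey window, and interval lengths (years)
  mid <- matrix(NA_real_, S, Ty)
  for (r in seq_len(nrow(sy_cells))) {
    s <- sy_cells[r, 1]; t <- sy_cells[r, 2]
    sel <- occ$gsite == s & occ$gyear == t
    mid[s, t] <- mean(as.numeric(occ$date[sel]))
  }
  dt_int <- matrix(NA_real_, S, Ty)  # interval t -> t+1 per site
  if (Ty > 1) {
    for (s in seq_len(S)) for (t in seq_len(Ty - 1)) {
      if (!is.na(mid[s, t]) && !is.na(mid[s, t + 1])) {
        dt_int[s, t] <- (mid[s, t + 1] - mid[s, t]) / DAYS_PER_YEAR
      }
    }
  }

  # spline spec frozen from observed SVL measurements at the CMR sites
  msvl <- dataset$events$svl_mm[dataset$events$site %in% sites]
  msvl <- msvl[!is.na(msvl)]
  spec <- spline_spec(msvl, n_knots = n_knots, degree = degree)

  N <- nrow(ind)
  site_i <- match(ind$site, sites)
  sex <- ind$sex
  ss_levels <- as.vector(outer(c("female", "male"), sites, paste, sep = "."))
  ssf <- match(paste("female", ind$site, sep = "."), ss_levels)
  ssm <- match(paste("male", ind$site, sep = "."), ss_levels)
  first_cal <- as.integer(format(ind$first_capture_date, "%Y"))
  first <- match(first_cal, years)
  stop_if(anyNA(first), "an individual's first capture year has no surveys")
  last <- vapply(site_i, function(s) max(which(occ_len[s, ] > 0L)),
                 integer(1))
  stop_if(any(first >= last),
          "individuals first captured in their site's final year must be ",
          "removed with filter_cmr_individuals() before fitting")

  # detections, flattened per individual over its site's occasions
  y_list <- vector("list", N)
  first_j <- integer(N)
  det_any <- matrix(0L, N, Ty)
  for (s in seq_len(S)) {
    dm <- detection_matrix(dataset, sites[s])
    rows <- which(site_i == s)
    occ_s <- occ[occ$gsite == s, , drop = FALSE]
    for (i in rows) {
      yv <- dm[ind$id[i], ]
      y_list[[i]] <- as.integer(yv)
      fo <- which(occ_s$date == ind$first_capture_date[i])
      stop_if(length(fo) != 1L, "first capture of '", ind$id[i],
              "' does not match a survey occasion")
      first_j[i] <- fo - 1L - (occ_off[s, first[i]] - site_base[s])
      stop_if(first_j[i] < 0L || first_j[i] >= occ_len[s, first[i]],
              "first capture of '", ind$id[i],
              "' is outside its first-year survey block")
      for (t in which(occ_len[s, ] > 0L)) {
        blk <- seq.int(occ_off[s, t] - site_base[s] + 1L,
                       length.out = occ_len[s, t])
        dets <- yv[blk]
        if (t == first[i]) {
          det_any[i, t] <- as.integer(any(dets[-seq_len(first_j[i] + 1L)]
                                          == 1L))
        } else if (t > first[i]) {
          det_any[i, t] <- as.integer(any(dets == 1L))
        }
      }
    }
  }
  y <- unlist(y_list)
  y_off <- c(0L, cumsum(lengths(y_list)))[seq_len(N)]

  # remeasurements (any measured capture after the first-capture event)
  ev <- dataset$events
  is_first <- paste(ev$individual_id, ev$date) %in%
    paste(ind$id, ind$first_capture_date)
  meas_ev <- ev[!is_first & !is.na(ev$svl_mm), , drop = FALSE]
  meas <- data.frame(
    ind = match(meas_ev$individual_id, ind$id),
    gyear = match(as.integer(format(meas_ev$date, "%Y")), years),
    svl = meas_ev$svl_mm
  )
  meas <- meas[!is.na(meas$ind) & !is.na(meas$gyear), , drop = FALSE]

  latents <- impute_missing_inputs(ind)
  lat_idx <- which(is.na(ind$first_svl_mm))
  lat_prior <- latents$latent_svl[match(ind$id[lat_idx],
                                        latents$latent_svl$id), ,
                                  drop = FALSE]

  # precomputed propagation structure: who grows into year t, and over what
  # interval
  prop_idx <- prop_dt <- vector("list", Ty)
  if (Ty > 1) {
    for (t in 2:Ty) {
      sel <- which(first <= t - 1L & last >= t)
      prop_idx[[t]] <- sel
      prop_dt[[t]] <- dt_int[cbind(site_i[sel], t - 1L)]
    }
  }
  inactive <- matrix(TRUE, N, Ty)
  for (i in seq_len(N)) inactive[i, first[i]:last[i]] <- FALSE

  list(
    N = N, S = S, Ty = Ty, sites = sites, years = years,
    ss_levels = ss_levels, ssf = ssf, ssm = ssm, site_i = site_i,
    sex = sex, first = first, last = last, first_svl = ind$first_svl_mm,
    lat_idx = lat_idx, lat_mean = lat_prior$prior_mean,
    lat_sd = lat_prior$prior_sd,
    unknown = which(sex == "unknown"),
    ids = ind$id,
    spec = spec, reference_svl = reference_svl,
    x_ref = std_apply(reference_svl, spec),
    W = W, cov_names = colnames(W), std = std,
    occ_off = occ_off, occ_len = occ_len, site_base = site_base,
    occ_sy_idx = occ_sy_idx, sy_cells = sy_cells, sy_labels = sy_labels,
    n_sy = nrow(sy_cells),
    y = y, y_off = y_off, first_j = first_j, det_any = det_any,
    dt_int = dt_int, meas = meas,
    prop_idx = prop_idx, prop_dt = prop_dt, inactive = inactive
  )
}

# ---------------------------------------------------------------------------
# likelihood pieces, cached by dependency

cmr_sizes <- function(st, dat) {
  m <- st$m
  ssx <- ifelse(m == 1, dat$ssm, dat$ssf)
  a <- st$upsilon_f + st$theta_m * m + st$eta[ssx]
  if (any(a <= 0)) return(NULL)
  logk <- st$mu_f + st$beta_m * m + st$alpha[ssx]
  k <- exp(outer(logk, st$zeta_k, `+`))  # N x Ty
  size <- matrix(0, dat$N, dat$Ty)
  fsvl <- dat$first_svl
  if (length(dat$lat_idx)) fsvl[dat$lat_idx] <- st$lat_svl
  size[cbind(seq_len(dat$N), dat$first)] <- fsvl
  if (dat$Ty > 1) {
    for (t in 2:dat$Ty) {
      sel <- dat$prop_idx[[t]]
      if (!length(sel)) next
      dt <- dat$prop_dt[[t]]
      size[sel, t] <- a[sel] - (a[sel] - size[sel, t - 1L]) *
        exp(-k[sel, t - 1L] * dt / a[sel])
    }
  }
  x <- (size - dat$spec$center) / dat$spec$scale
  x[dat$inactive] <- 0
  list(ssx = ssx, a = a, size = size, x = x,
       B = spline_basis(as.vector(x), dat$spec, standardized = TRUE))
}

cmr_meas_ll <- function(st, cache, dat) {
  if (!nrow(dat$meas)) return(rep(0, dat$N))
  v <- dnorm(dat$meas$svl,
             cache$size[cbind(dat$meas$ind, dat$meas$gyear)],
             st$sigma_e, log = TRUE)
  rowsum_safe(v, dat$meas$ind, dat$N)
}

cmr_phi <- function(st, cache, dat) {
  f <- matrix(cache$B %*% c(st$q_phi, st$b_phi), dat$N, dat$Ty)
  plogis(st$pi_phi[cache$ssx] + f + rep(st$xi, each = dat$N))
}

cmr_gamma <- function(st, cache, dat) {
  nu_full <- matrix(0, dat$S, dat$Ty)
  nu_full[dat$sy_cells] <- st$nu
  plogis(st$zeta_g[cache$ssx] + st$lambda * cache$x +
           nu_full[dat$site_i, , drop = FALSE])
}

cmr_cmat <- function(st, cache, dat) {
  f <- matrix(cache$B %*% c(st$q_p, st$b_p), dat$N, dat$Ty)
  st$o_p[cache$ssx] + f
}

cmr_u <- function(st, dat) {
  drop(dat$W %*% st$delta) + st$omega[dat$occ_sy_idx]
}

cmr_forward <- function(cache, dat) {
  cmr_forward_cpp(dat$first, dat$last, dat$site_i,
                  cache$phi, cache$gamma, cache$cmat, cache$u,
                  dat$occ_off, dat$occ_len, dat$site_base,
                  dat$y, dat$y_off, dat$first_j, dat$det_any)
}

# dependency codes: 1 sizes (implies everything downstream), 2 phi,
# 3 gamma, 4 cmat, 5 u, 6 meas only.  Returns NULL for out-of-domain
# states.
cmr_update_cache <- function(st, dat, cache, code) {
  if (code == 1L) {
    sz <- cmr_sizes(st, dat)
    if (is.null(sz)) return(NULL)
    cache[names(sz)] <- sz
    cache$meas_ll <- cmr_meas_ll(st, cache, dat)
    cache$phi <- cmr_phi(st, cache, dat)
    cache$gamma <- cmr_gamma(st, cache, dat)
    cache$cmat <- cmr_cmat(st, cache, dat)
    cache$u <- cmr_u(st, dat)
  } else if (code == 2L) {
    cache$phi <- cmr_phi(st, cache, dat)
  } else if (code == 3L) {
    cache$gamma <- cmr_gamma(st, cache, dat)
  } else if (code == 4L) {
    cache$cmat <- cmr_cmat(st, cache, dat)
  } else if (code == 5L) {
    cache$u <- cmr_u(st, dat)
  } else if (code == 7L) {
    cache$cmat <- cmr_cmat(st, cache, dat)
    cache$u <- cmr_u(st, dat)
  } else if (code == 6L) {
    cache$meas_ll <- cmr_meas_ll(st, cache, dat)
    return(cache)
  }
  cache$llvec <- cmr_forward(cache, dat)
  cache
}

cmr_cache_full <- function(st, dat) {
  cmr_update_cache(st, dat, list(), 1L)
}

bvn_logdens <- function(z1, z2, s1, s2, rho) {
  q <- (z1 / s1)^2 - 2 * rho * (z1 / s1) * (z2 / s2) + (z2 / s2)^2
  sum(-log(2 * pi) - log(s1 * s2) - 0.5 * log1p(-rho^2) -
        q / (2 * (1 - rho^2)))
}

growth_prior_entry <- function(entries, label, fallback) {
  if (is.null(entries)) return(fallback)
  if (!is.null(entries[[label]])) return(entries[[label]])
  fallback
}

# Flatten the prior specification into plain numeric hyperparameters so the
# per-iteration prior evaluation is free of list lookups.
cmr_prior_prep <- function(dat, pr) {
  g <- pr$growth
  eta_fb <- list(family = "normal", mean = 0, sd = 50)
  alpha_fb <- list(family = "normal", mean = 0, sd = 1)
  eta_sp <- lapply(dat$ss_levels, function(ss) {
    growth_prior_entry(g$eta, paste0("eta[", ss, "]"), eta_fb)
  })
  alpha_sp <- lapply(dat$ss_levels, function(ss) {
    growth_prior_entry(g$alpha, paste0("alpha[", ss, "]"), alpha_fb)
  })
  list(
    delta_mean = pr$delta_p$mean, delta_sd = pr$delta_p$sd,
    lambda_mean = pr$lambda_gamma$mean, lambda_sd = pr$lambda_gamma$sd,
    sd_rates = c(phi = pr$sigma_phi_year$rate, p = pr$sigma_p_year$rate,
                 gamma = pr$sigma_gamma_year$rate, b = pr$sigma_b$rate),
    lsk_mean = g$log_sigma_k_year$mean, lsk_sd = g$log_sigma_k_year$sd,
    lse_mean = g$log_sigma_e$mean, lse_sd = g$log_sigma_e$sd,
    gl_mean = c(g$upsilon_f$mean, g$theta_m$mean, g$mu_f$mean,
                g$beta_m$mean),
    gl_sd = c(g$upsilon_f$sd, g$theta_m$sd, g$mu_f$sd, g$beta_m$sd),
    eta_mean = vapply(eta_sp, `[[`, numeric(1), "mean"),
    eta_sd = vapply(eta_sp, `[[`, numeric(1), "sd"),
    alpha_mean = vapply(alpha_sp, `[[`, numeric(1), "mean"),
    alpha_sd = vapply(alpha_sp, `[[`, numeric(1), "sd")
  )
}

cmr_log_prior <- function(st, dat, pp) {
  if (abs(st$rho) >= 1) return(-Inf)
  dexp_l <- function(x, rate) log(rate) - rate * x
  sum(dlogis(c(st$pi_phi, st$o_p, st$zeta_g), log = TRUE)) +
    sum(dnorm(st$delta, pp$delta_mean, pp$delta_sd, log = TRUE)) +
    dnorm(st$lambda, pp$lambda_mean, pp$lambda_sd, log = TRUE) +
    dnorm(st$q_phi, 0, 1, log = TRUE) + dnorm(st$q_p, 0, 1, log = TRUE) +
    sum(dnorm(st$b_phi, 0, st$sigma_b_phi, log = TRUE)) +
    sum(dnorm(st$b_p, 0, st$sigma_b_p, log = TRUE)) +
    sum(dnorm(st$omega, 0, st$sigma_p_year, log = TRUE)) +
    sum(dnorm(st$nu, 0, st$sigma_gamma_year, log = TRUE)) +
    bvn_logdens(st$zeta_k, st$xi, st$sigma_k_year, st$sigma_phi_year,
                st$rho) +
    # SDs sampled on the log scale: exponential density + Jacobian, except
    # the stage-1-transferred SDs whose priors are already on the log scale
    dexp_l(st$sigma_phi_year, pp$sd_rates[[1]]) + log(st$sigma_phi_year) +
    dexp_l(st$sigma_p_year, pp$sd_rates[[2]]) + log(st$sigma_p_year) +
    dexp_l(st$sigma_gamma_year, pp$sd_rates[[3]]) +
    log(st$sigma_gamma_year) +
    dexp_l(st$sigma_b_phi, pp$sd_rates[[4]]) + log(st$sigma_b_phi) +
    dexp_l(st$sigma_b_p, pp$sd_rates[[4]]) + log(st$sigma_b_p) +
    dnorm(log(st$sigma_k_year), pp$lsk_mean, pp$lsk_sd, log = TRUE) +
    dnorm(log(st$sigma_e), pp$lse_mean, pp$lse_sd, log = TRUE) +
    sum(dnorm(c(st$upsilon_f, st$theta_m, st$mu_f, st$beta_m),
              pp$gl_mean, pp$gl_sd, log = TRUE)) +
    sum(dnorm(st$eta, pp$eta_mean, pp$eta_sd, log = TRUE)) +
    sum(dnorm(st$alpha, pp$alpha_mean, pp$alpha_sd, log = TRUE))
}

cmr_lat_prior_vec <- function(st, dat) {
  if (!length(dat$lat_idx)) return(numeric(0))
  dnorm(st$lat_svl, dat$lat_mean, dat$lat_sd, log = TRUE)
}

# ---------------------------------------------------------------------------
# sampler

cmr_init_state <- function(dat, pr, init) {
  nSS <- length(dat$ss_levels)
  g <- pr$growth
  gmean <- function(entry, fallback) {
    if (!is.null(entry$mean) && abs(entry$sd) < 100) entry$mean else fallback
  }
  st <- list(
    pi_phi = rnorm(nSS, 0.4, 0.2), xi = rnorm(dat$Ty, 0, 0.05),
    q_phi = 0, b_phi = rep(0, dat$spec$n_knots),
    o_p = rnorm(nSS, -4, 0.2), delta = rep(0, ncol(dat$W)),
    q_p = 0, b_p = rep(0, dat$spec$n_knots),
    omega = rep(0, dat$n_sy),
    zeta_g = rnorm(nSS, 0, 0.2), lambda = 0.1, nu = rep(0, dat$n_sy),
    rho = 0,
    sigma_phi_year = 0.5, sigma_p_year = 0.5, sigma_gamma_year = 0.5,
    sigma_b_phi = 0.3, sigma_b_p = 0.3,
    sigma_k_year = exp(gmean(g$log_sigma_k_year, log(0.2))),
    sigma_e = exp(gmean(g$log_sigma_e, log(20))),
    upsilon_f = gmean(g$upsilon_f, 737) + rnorm(1, 0, 5),
    theta_m = gmean(g$theta_m, -187) + rnorm(1, 0, 5),
    mu_f = gmean(g$mu_f, 5.5) + rnorm(1, 0, 0.05),
    beta_m = gmean(g$beta_m, 0.3) + rnorm(1, 0, 0.05),
    eta = rnorm(nSS, 0, 2), alpha = rnorm(nSS, 0, 0.05),
    zeta_k = rnorm(dat$Ty, 0, 0.02),
    lat_svl = dat$lat_mean + rnorm(length(dat$lat_idx), 0, 5),
    m = as.numeric(dat$sex == "male")
  )
  st$m[dat$unknown] <- rbinom(length(dat$unknown), 1, 0.5)
  if (!is.null(init)) st[names(init)] <- init
  st
}

# registry of update components: field, indices, dependency code, proposal
# type.  Structural scalars get single-site updates (acceptance target
# 0.44); random-effect and coefficient vectors are updated jointly
# (target 0.234).  Fields named in `fix` are held at their initial values.
cmr_component_registry <- function(dat, fix = character()) {
  nSS <- length(dat$ss_levels); G <- dat$spec$n_knots
  reg <- list()
  add <- function(field, n, code, type = "rw", scale = 0.2,
                  block = FALSE) {
    if (field %in% fix) return(invisible(NULL))
    if (block) {
      reg[[length(reg) + 1L]] <<- list(field = field, j = seq_len(n),
                                       code = code, type = type,
                                       scale = scale / sqrt(n),
                                       target = 0.234)
    } else {
      for (j in seq_len(n)) {
        reg[[length(reg) + 1L]] <<- list(field = field, j = j, code = code,
                                         type = type, scale = scale,
                                         target = 0.44)
      }
    }
  }
  add("pi_phi", nSS, 2L, scale = 0.3)
  add("xi", dat$Ty, 2L, scale = 0.5, block = TRUE)
  add("q_phi", 1, 2L)
  add("b_phi", G, 2L, scale = 0.4, block = TRUE)
  add("o_p", nSS, 4L, scale = 0.3)
  add("delta", ncol(dat$W), 5L, scale = 0.2, block = TRUE)
  add("q_p", 1, 4L)
  add("b_p", G, 4L, scale = 0.4, block = TRUE)
  add("omega", dat$n_sy, 5L, scale = 0.6, block = TRUE)
  add("zeta_g", nSS, 3L, scale = 0.4)
  add("lambda", 1, 3L, scale = 0.3)
  add("nu", dat$n_sy, 3L, scale = 0.8, block = TRUE)
  add("zeta_k", dat$Ty, 1L, scale = 0.15, block = TRUE)
  add("upsilon_f", 1, 1L, scale = 8)
  add("theta_m", 1, 1L, scale = 8)
  add("eta", nSS, 1L, scale = 5)
  add("mu_f", 1, 1L, scale = 0.1)
  add("beta_m", 1, 1L, scale = 0.1)
  add("alpha", nSS, 1L, scale = 0.1)
  add("sigma_e", 1, 6L, type = "log", scale = 0.1)
  for (nm in c("sigma_phi_year", "sigma_p_year", "sigma_gamma_year",
               "sigma_k_year", "sigma_b_phi", "sigma_b_p")) {
    add(nm, 1, 0L, type = "log", scale = 0.3)
  }
  add("rho", 1, 0L, scale = 0.3)

  # translation moves along likelihood-invariant ridges: shift an intercept
  # set one way and its random-effect vector the other, so the linear
  # predictors are unchanged and the prior decides.  Without these the
  # intercepts and their effect vectors mix very slowly.
  male_cells <- grep("^male\\.", dat$ss_levels)
  trans <- function(fn, code, scale) {
    reg[[length(reg) + 1L]] <<- list(field = NULL, j = 1L, code = code,
                                     type = "rw", scale = scale,
                                     target = 0.44, trans = fn)
  }
  if (!"pi_phi" %in% fix && !"xi" %in% fix) {
    trans(function(st, d) { st$pi_phi <- st$pi_phi + d
                            st$xi <- st$xi - d; st }, 2L, 0.5)
  }
  if (!"o_p" %in% fix && !"omega" %in% fix) {
    trans(function(st, d) { st$o_p <- st$o_p + d
                            st$omega <- st$omega - d; st }, 7L, 0.5)
  }
  if (!"zeta_g" %in% fix && !"nu" %in% fix) {
    trans(function(st, d) { st$zeta_g <- st$zeta_g + d
                            st$nu <- st$nu - d; st }, 3L, 0.5)
  }
  if (!"upsilon_f" %in% fix && !"eta" %in% fix) {
    trans(function(st, d) { st$upsilon_f <- st$upsilon_f + d
                            st$eta <- st$eta - d; st }, 1L, 5)
    trans(function(st, d) { st$theta_m <- st$theta_m + d
                            st$eta[male_cells] <- st$eta[male_cells] - d
                            st }, 1L, 5)
  }
  if (!"mu_f" %in% fix && !"alpha" %in% fix) {
    trans(function(st, d) { st$mu_f <- st$mu_f + d
                            st$alpha <- st$alpha - d; st }, 1L, 0.1)
    trans(function(st, d) { st$beta_m <- st$beta_m + d
                            st$alpha[male_cells] <- st$alpha[male_cells] - d
                            st }, 1L, 0.1)
    trans(function(st, d) { st$mu_f <- st$mu_f + d
                            st$zeta_k <- st$zeta_k - d; st }, 1L, 0.05)
  }
  reg
}

cmr_sample_chain <- function(dat, pr, mcmc, seed, init,
                             fix = character()) {
  set.seed(seed %% .Machine$integer.max)
  st <- cmr_init_state(dat, pr, init)
  cache <- cmr_cache_full(st, dat)
  stop_if(is.null(cache), "initial state outside the model domain")
  pp <- cmr_prior_prep(dat, pr)
  lp <- cmr_log_prior(st, dat, pp)
  lat_lp <- cmr_lat_prior_vec(st, dat)
  post <- sum(cache$llvec) + sum(cache$meas_ll) + lp + sum(lat_lp)
  stop_if(!is.finite(post), "initial state has zero posterior density")

  reg <- cmr_component_registry(dat, fix)
  ad <- adapt_state(length(reg))
  for (c in seq_along(reg)) {
    ad$log_scale[c] <- log(reg[[c]]$scale)
    ad$target[c] <- reg[[c]]$target
  }
  n_lat <- length(dat$lat_idx)
  ad_lat <- adapt_state(max(n_lat, 1L), init_scale = 10)

  G <- dat$spec$n_knots
  cols <- c(paste0("pi_phi[", dat$ss_levels, "]"),
            paste0("xi[", dat$years, "]"),
            "q_phi", paste0("b_phi[", seq_len(G), "]"), "sigma_b_phi",
            "sigma_phi_year",
            paste0("o_p[", dat$ss_levels, "]"),
            paste0("delta_p[", dat$cov_names, "]"),
            "q_p", paste0("b_p[", seq_len(G), "]"), "sigma_b_p",
            paste0("omega[", dat$sy_labels, "]"), "sigma_p_year",
            paste0("zeta_gamma[", dat$ss_levels, "]"), "lambda_gamma",
            paste0("nu[", dat$sy_labels, "]"), "sigma_gamma_year",
            "rho_k_phi",
            "upsilon_f", "theta_m", paste0("eta[", dat$ss_levels, "]"),
            "mu_f", "beta_m", paste0("alpha[", dat$ss_levels, "]"),
            paste0("zeta_k[", dat$years, "]"), "sigma_k_year", "sigma_e",
            if (n_lat) paste0("svl0[", dat$ids[dat$lat_idx], "]"),
            if (length(dat$unknown)) paste0("male[", dat$ids[dat$unknown],
                                            "]"),
            paste0("phi_mean[", dat$ss_levels, "]"),
            paste0("p_mean[", dat$ss_levels, "]"),
            paste0("gamma_mean[", dat$ss_levels, "]"))
  out <- matrix(NA_real_, mcmc$draws, length(cols),
                dimnames = list(NULL, cols))
  keep_row <- 0L
  bref <- drop(spline_basis(dat$x_ref, dat$spec, standardized = TRUE))

  n_iter <- mcmc$warmup + mcmc$draws * mcmc$thin
  for (iter in seq_len(n_iter)) {
    for (c in seq_along(reg)) {
      cmp <- reg[[c]]
      step <- exp(ad$log_scale[c]) * rnorm(length(cmp$j))
      if (!is.null(cmp$trans)) {
        st2 <- cmp$trans(st, step)
      } else {
        st2 <- st
        if (cmp$type == "log") {
          st2[[cmp$field]][cmp$j] <- st[[cmp$field]][cmp$j] * exp(step)
        } else {
          st2[[cmp$field]][cmp$j] <- st[[cmp$field]][cmp$j] + step
        }
      }
      cache2 <- if (cmp$code > 0L) {
        cmr_update_cache(st2, dat, cache, cmp$code)
      } else cache
      ad$attempted[c] <- ad$attempted[c] + 1
      if (is.null(cache2)) next
      lp2 <- cmr_log_prior(st2, dat, pp)
      post2 <- sum(cache2$llvec) + sum(cache2$meas_ll) + lp2 + sum(lat_lp)
      acc <- is.finite(post2) && log(runif(1)) < post2 - post
      if (acc) {
        st <- st2; cache <- cache2; lp <- lp2; post <- post2
        ad$accepted[c] <- ad$accepted[c] + 1
      }
    }
    # latent first-capture sizes: propose all, accept elementwise
    if (n_lat) {
      st2 <- st
      st2$lat_svl <- st$lat_svl + exp(ad_lat$log_scale) * rnorm(n_lat)
      cache2 <- cmr_update_cache(st2, dat, cache, 1L)
      if (!is.null(cache2)) {
        lat_lp2 <- cmr_lat_prior_vec(st2, dat)
        li <- dat$lat_idx
        d_old <- cache$llvec[li] + cache$meas_ll[li] + lat_lp
        d_new <- cache2$llvec[li] + cache2$meas_ll[li] + lat_lp2
        acc_i <- log(runif(n_lat)) < d_new - d_old
        if (any(acc_i)) {
          st$lat_svl[acc_i] <- st2$lat_svl[acc_i]
          cache <- cmr_update_cache(st, dat, cache, 1L)
          lat_lp <- cmr_lat_prior_vec(st, dat)
          post <- sum(cache$llvec) + sum(cache$meas_ll) + lp + sum(lat_lp)
        }
        ad_lat$attempted <- ad_lat$attempted + 1
        ad_lat$accepted <- ad_lat$accepted + as.numeric(acc_i)
      }
    }
    # latent sex: Gibbs, exploiting per-individual factorization
    if (length(dat$unknown)) {
      st0 <- st; st0$m[dat$unknown] <- 0
      st1 <- st; st1$m[dat$unknown] <- 1
      c0 <- cmr_update_cache(st0, dat, cache, 1L)
      c1 <- cmr_update_cache(st1, dat, cache, 1L)
      if (!is.null(c0) && !is.null(c1)) {
        for (uidx in dat$unknown) {
          l0 <- c0$llvec[uidx] + c0$meas_ll[uidx]
          l1 <- c1$llvec[uidx] + c1$meas_ll[uidx]
          st$m[uidx] <- rbinom(1, 1, 1 / (1 + exp(l0 - l1)))
        }
        cache <- cmr_update_cache(st, dat, cache, 1L)
        post <- sum(cache$llvec) + sum(cache$meas_ll) + lp + sum(lat_lp)
      }
    }

    ad <- adapt_maybe_update(ad, iter, mcmc$warmup)
    ad_lat <- adapt_maybe_update(ad_lat, iter, mcmc$warmup)

    if (iter > mcmc$warmup && (iter - mcmc$warmup) %% mcmc$thin == 0L) {
      keep_row <- keep_row + 1L
      fphi_ref <- sum(bref * c(st$q_phi, st$b_phi))
      fp_ref <- sum(bref * c(st$q_p, st$b_p))
      out[keep_row, ] <- c(
        st$pi_phi, st$xi, st$q_phi, st$b_phi, st$sigma_b_phi,
        st$sigma_phi_year, st$o_p, st$delta, st$q_p, st$b_p, st$sigma_b_p,
        st$omega, st$sigma_p_year, st$zeta_g, st$lambda, st$nu,
        st$sigma_gamma_year, st$rho,
        st$upsilon_f, st$theta_m, st$eta, st$mu_f, st$beta_m, st$alpha,
        st$zeta_k, st$sigma_k_year, st$sigma_e,
        if (n_lat) st$lat_svl, if (length(dat$unknown)) st$m[dat$unknown],
        plogis(st$pi_phi + fphi_ref),
        plogis(st$o_p + fp_ref),
        plogis(st$zeta_g + st$lambda * dat$x_ref))
    }
  }
  out
}

#' Fit the joint growth and robust-design survival model
#'
#' Samples the joint posterior of the three-state robust-design CJS model
#' with penalized-spline size effects on survival and daily capture
#' probability, a linear size effect on availability, an embedded von
#' Bertalanffy growth block that propagates each individual's latent size
#' across primary periods, correlated annual random effects on growth rate
#' and survival (bivariate normal with correlation `rho`), latent
#' first-capture sizes for unmeasured individuals, and latent sex
#' indicators (Bernoulli(0.5)) for unknown-sex individuals.  The
#' marginalized forward-algorithm likelihood implements the known-available
#' rule: occasions on which an individual was temporarily unavailable
#' contribute no information about capture probability.
#'
#' @param dataset a `capture_dataset` restricted to the CMR sites and
#'   filtered with [filter_cmr_individuals()].
#' @param growth_stage1 optional `vb_growth_fit`; its posterior becomes the
#'   informative prior of the growth block (widened by `priors$inflation`).
#' @param priors from [cmr_priors()]; built from `growth_stage1` when NULL.
#' @param mcmc from [mcmc_config()].
#' @param seed integer seed.
#' @param n_knots,degree penalized-spline settings (defaults 5 knots,
#'   cubic).
#' @param reference_svl SVL (mm) at which mean survival/capture/availability
#'   are reported (default 463, an average adult).
#' @param init optional named list overriding initial values.
#' @param fix character vector of parameter fields to hold at their initial
#'   values (e.g. `"sigma_b_phi"` to study the shrinkage limit of the
#'   survival smooth).
#' @return object of class `vb_cmr_fit` with `draws`, `convergence`,
#'   `model_data`, `spline_spec`, `sex_site_levels`, `priors`, `mcmc`,
#'   `seed`.
#' @export
fit_cmr <- function(dataset, growth_stage1 = NULL, priors = NULL,
                    mcmc = mcmc_config(), seed = 1L, n_knots = 5L,
                    degree = 3L, reference_svl = 463, init = NULL,
                    fix = character()) {
  priors <- priors %||% cmr_priors(growth_stage1)
  dat <- cmr_model_data(dataset, n_knots = n_knots, degree = degree,
                        reference_svl = reference_svl)
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    cmr_sample_chain(dat, priors, mcmc, chain_seed(seed, ch), init, fix)
  })
  draws <- posterior_draws(chains)
  core <- c(paste0("phi_mean[", dat$ss_levels, "]"),
            paste0("p_mean[", dat$ss_levels, "]"),
            paste0("gamma_mean[", dat$ss_levels, "]"),
            paste0("delta_p[", dat$cov_names, "]"),
            "lambda_gamma", "sigma_phi_year", "sigma_p_year",
            "sigma_gamma_year", "upsilon_f", "theta_m", "mu_f", "beta_m",
            "sigma_e")
  sub <- posterior_draws(lapply(draws$chains,
                                function(ch) ch[, core, drop = FALSE]))
  structure(list(draws = draws, convergence = convergence_report(sub),
                 model_data = dat, spline_spec = dat$spec,
                 sex_site_levels = dat$ss_levels, priors = priors,
                 mcmc = mcmc, seed = seed),
            class = "vb_cmr_fit")
}

#' @export
print.vb_cmr_fit <- function(x, ...) {
  cat("Joint growth + robust-design CJS fit:",
      length(x$draws$chains), "chains x", nrow(x$draws$chains[[1]]),
      "draws;", x$model_data$N, "individuals,", x$model_data$S, "site(s),",
      x$model_data$Ty, "primary periods\n")
  cat("max split R-hat (core parameters):",
      round(x$convergence$max_rhat, 3),
      if (x$convergence$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# posterior-predictive support

cmr_state_from_draw <- function(drawvec, dat) {
  G <- dat$spec$n_knots
  gv <- function(labs) unname(drawvec[labs])
  st <- list(
    pi_phi = gv(paste0("pi_phi[", dat$ss_levels, "]")),
    xi = gv(paste0("xi[", dat$years, "]")),
    q_phi = drawvec[["q_phi"]], b_phi = gv(paste0("b_phi[", 1:G, "]")),
    o_p = gv(paste0("o_p[", dat$ss_levels, "]")),
    delta = gv(paste0("delta_p[", dat$cov_names, "]")),
    q_p = drawvec[["q_p"]], b_p = gv(paste0("b_p[", 1:G, "]")),
    omega = gv(paste0("omega[", dat$sy_labels, "]")),
    zeta_g = gv(paste0("zeta_gamma[", dat$ss_levels, "]")),
    lambda = drawvec[["lambda_gamma"]],
    nu = gv(paste0("nu[", dat$sy_labels, "]")),
    rho = drawvec[["rho_k_phi"]],
    sigma_phi_year = drawvec[["sigma_phi_year"]],
    sigma_p_year = drawvec[["sigma_p_year"]],
    sigma_gamma_year = drawvec[["sigma_gamma_year"]],
    sigma_b_phi = drawvec[["sigma_b_phi"]],
    sigma_b_p = drawvec[["sigma_b_p"]],
    sigma_k_year = drawvec[["sigma_k_year"]],
    sigma_e = drawvec[["sigma_e"]],
    upsilon_f = drawvec[["upsilon_f"]], theta_m = drawvec[["theta_m"]],
    mu_f = drawvec[["mu_f"]], beta_m = drawvec[["beta_m"]],
    eta = gv(paste0("eta[", dat$ss_levels, "]")),
    alpha = gv(paste0("alpha[", dat$ss_levels, "]")),
    zeta_k = gv(paste0("zeta_k[", dat$years, "]")),
    lat_svl = if (length(dat$lat_idx))
      gv(paste0("svl0[", dat$ids[dat$lat_idx], "]")) else numeric(0),
    m = as.numeric(dat$sex == "male")
  )
  if (length(dat$unknown)) {
    st$m[dat$unknown] <- gv(paste0("male[", dat$ids[dat$unknown], "]"))
  }
  st
}

# probability of >= 1 detection per individual and primary, given available
# (for the release primary: over occasions after the initial capture)
cmr_pstar <- function(st, cache, dat) {
  pstar <- matrix(0, dat$N, dat$Ty)
  for (r in seq_len(nrow(dat$sy_cells))) {
    s <- dat$sy_cells[r, 1]; t <- dat$sy_cells[r, 2]
    rows <- which(dat$site_i == s & dat$first <= t & dat$last >= t)
    if (!length(rows)) next
    og <- dat$occ_off[s, t]
    jj <- seq.int(og + 1L, length.out = dat$occ_len[s, t])
    lp <- outer(cache$cmat[rows, t], cache$u[jj], `+`)
    log_mis <- rowSums(plogis(lp, log.p = TRUE, lower.tail = FALSE))
    pstar[rows, t] <- -expm1(log_mis)
    at_first <- rows[dat$first[rows] == t]
    for (i in at_first) {
      keep <- seq_along(jj) > dat$first_j[i] + 1L
      lm <- if (any(keep)) {
        sum(plogis(cache$cmat[i, t] + cache$u[jj[keep]], log.p = TRUE,
                   lower.tail = FALSE))
      } else 0
      pstar[i, t] <- -expm1(lm)
    }
  }
  pstar
}

# one-step-ahead probability of being available, filtered on a detection
# indicator matrix (conditional mode) or unconditional (marginal mode)
cmr_prob_available <- function(det, pstar, cache, dat, mode) {
  prA <- matrix(0, dat$N, dat$Ty)
  fA <- fU <- fD <- numeric(dat$N)
  for (i in seq_len(dat$N)) fA[i] <- 1
  prA[cbind(seq_len(dat$N), dat$first)] <- 1
  if (dat$Ty < 2) return(prA)
  for (t in 2:dat$Ty) {
    act <- which(dat$first <= t - 1L & dat$last >= t)
    if (!length(act)) next
    ps <- cache$phi[act, t - 1L]; g <- cache$gamma[act, t]
    AU <- fA[act] + fU[act]
    A2 <- AU * ps * g; U2 <- AU * ps * (1 - g); D2 <- fD[act] + AU * (1 - ps)
    tot <- A2 + U2 + D2
    prA[act, t] <- A2 / tot
    if (mode == "conditional") {
      d <- det[act, t]
      pA <- A2 * ifelse(d == 1, pstar[act, t], 1 - pstar[act, t])
      pU <- U2 * (d == 0); pD <- D2 * (d == 0)
      nrm <- pmax(pA + pU + pD, .Machine$double.xmin)
      fA[act] <- pA / nrm; fU[act] <- pU / nrm; fD[act] <- pD / nrm
    } else {
      fA[act] <- A2 / tot; fU[act] <- U2 / tot; fD[act] <- D2 / tot
    }
    fresh <- which(dat$first == t)  # individuals released in t
    fA[fresh] <- 1; fU[fresh] <- 0; fD[fresh] <- 0
  }
  prA
}

cmr_active_cells <- function(dat) {
  act <- matrix(FALSE, dat$N, dat$Ty)
  for (i in seq_len(dat$N)) act[i, dat$first[i]:dat$last[i]] <- TRUE
  act
}

cmr_ppc_one_draw <- function(drawvec, fit, mode) {
  dat <- fit$model_data
  st <- cmr_state_from_draw(drawvec, dat)
  cache <- cmr_cache_full(st, dat)
  stop_if(is.null(cache), "posterior draw outside the model domain")
  pstar <- cmr_pstar(st, cache, dat)
  act <- cmr_active_cells(dat)

  # replicate detection indicators simulated from this draw
  avail <- alive <- matrix(FALSE, dat$N, dat$Ty)
  alive[cbind(seq_len(dat$N), dat$first)] <- TRUE
  avail[cbind(seq_len(dat$N), dat$first)] <- TRUE
  if (dat$Ty > 1) {
    for (t in 2:dat$Ty) {
      sel <- which(dat$first <= t - 1L & dat$last >= t)
      if (!length(sel)) next
      sv <- alive[sel, t - 1L] &
        (runif(length(sel)) < cache$phi[sel, t - 1L])
      alive[sel, t] <- sv
      avail[sel, t] <- sv & (runif(length(sel)) < cache$gamma[sel, t])
    }
  }
  rep_det <- matrix(0L, dat$N, dat$Ty)
  rep_det[avail] <- as.integer(runif(sum(avail)) < pstar[avail])

  prA_obs <- cmr_prob_available(dat$det_any, pstar, cache, dat, mode)
  exp_obs <- prA_obs * pstar
  t_obs <- freeman_tukey(dat$det_any[act], exp_obs[act])
  prA_rep <- if (mode == "conditional") {
    cmr_prob_available(rep_det, pstar, cache, dat, mode)
  } else prA_obs
  exp_rep <- prA_rep * pstar
  t_rep <- freeman_tukey(rep_det[act], exp_rep[act])
  list(t_obs = t_obs, t_rep = t_rep)
}
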