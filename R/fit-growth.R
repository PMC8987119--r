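# Hierarchical von Bertalanffy growth model: data preparation, posterior
# density, adaptive Metropolis-within-Gibbs sampler, and size-at-age
# projection.

# Build index structures from an increment table.
growth_model_data <- function(increments) {
  stop_if(nrow(increments) < 1L, "need at least one growth increment")
  inc <- increments
  ids <- sort(unique(inc$individual_id))
  ind <- match(inc$individual_id, ids)
  # per-individual sex ("female"/"male"/"unknown") and site
  sex_i <- vapply(split(inc$sex, ind), function(s) s[1], character(1))
  site_i <- vapply(split(inc$site, ind), function(s) s[1], character(1))
  sites <- sort(unique(site_i))
  groups <- as.vector(outer(c("female", "male"), sites, paste, sep = "."))
  gf <- match(paste("female", site_i[ind], sep = "."), groups)
  gm <- match(paste("male", site_i[ind], sep = "."), groups)

  segs <- lapply(seq_len(nrow(inc)), function(j) {
    increment_year_segments(inc$start_date[j], inc$end_date[j])
  })
  years <- sort(unique(unlist(lapply(segs, `[[`, "year"))))
  dt_mat <- matrix(0, nrow(inc), length(years))
  for (j in seq_along(segs)) {
    dt_mat[j, match(segs[[j]]$year, years)] <- segs[[j]]$dt_years
  }

  list(
    n_inc = nrow(inc), l_start = inc$l_start_mm, l_end = inc$l_end_mm,
    ind = ind, ids = ids, n_ind = length(ids),
    sex = sex_i, site = site_i, groups = groups, gf = gf, gm = gm,
    years = years, dt_mat = dt_mat,
    unknown = which(sex_i == "unknown")
  )
}

# Expected end length per increment under a full parameter state.
growth_mu_vec <- function(st, dat) {
  m_inc <- st$m[dat$ind]
  grp <- ifelse(m_inc == 1, dat$gm, dat$gf)
  a <- st$upsilon_f + st$theta_m * m_inc + st$eta[grp]
  if (any(a <= 0)) return(NULL)  # outside the kernel's domain
  base <- st$mu_f + st$beta_m * m_inc + st$alpha[grp] + st$iota[dat$ind]
  w <- drop(dat$dt_mat %*% exp(st$zeta))
  a - (a - dat$l_start) * exp(-exp(base) * w / a)
}

growth_ll_vec <- function(st, dat) {
  mu <- growth_mu_vec(st, dat)
  if (is.null(mu)) return(rep(-Inf, dat$n_inc))
  dnorm(dat$l_end, mu, st$sigma_e, log = TRUE)
}

growth_log_prior <- function(st, pr) {
  prior_logdens(st$upsilon_f, pr$upsilon_f) +
    prior_logdens(st$theta_m, pr$theta_m) +
    prior_logdens(st$mu_f, pr$mu_f) +
    prior_logdens(st$beta_m, pr$beta_m) +
    # sigmas sampled on the log scale: prior density + Jacobian log(sigma)
    prior_logdens(st$sigma_k_year, pr$sigma_k_year) + log(st$sigma_k_year) +
    prior_logdens(st$sigma_k_site, pr$sigma_k_site) + log(st$sigma_k_site) +
    prior_logdens(st$sigma_k_indiv, pr$sigma_k_indiv) + log(st$sigma_k_indiv) +
    prior_logdens(st$sigma_a_site, pr$sigma_a_site) + log(st$sigma_a_site) +
    prior_logdens(st$sigma_e, pr$sigma_e) + log(st$sigma_e) +
    sum(dnorm(st$eta, 0, st$sigma_a_site, log = TRUE)) +
    sum(dnorm(st$alpha, 0, st$sigma_k_site, log = TRUE)) +
    sum(dnorm(st$zeta, 0, st$sigma_k_year, log = TRUE))
}

# iota prior handled separately (needed per-individual for vector updates)
growth_iota_prior_vec <- function(st) dnorm(st$iota, 0, st$sigma_k_indiv,
                                            log = TRUE)

#' Fit the hierarchical von Bertalanffy growth model
#'
#' Samples the joint posterior of the growth parameters by adaptive
#' Metropolis-within-Gibbs: scalar random-walk updates for fixed effects,
#' random effects and (log) standard deviations, a vectorized elementwise
#' update for the individual growth-rate effects, and a Gibbs draw for the
#' latent male indicator of unknown-sex individuals (Bernoulli(0.5) prior).
#' Increments spanning several calendar years are segmented at year
#' boundaries so year effects act on the time actually spent in each year.
#'
#' @param data a `capture_dataset` (increments are built from its events) or
#'   a growth-increment data frame from [build_growth_increments()].
#' @param priors from [growth_priors()].
#' @param mcmc from [mcmc_config()].
#' @param seed integer seed; fits are reproducible given seed and config.
#' @param init optional named list overriding initial values.
#' @return object of class `vb_growth_fit`: `draws` ([posterior_draws()]
#'   including derived `mu_a_m = upsilon_f + theta_m` and
#'   `mu_k_m = mu_f + beta_m`), `convergence` (split R-hat report),
#'   `model_data`, `priors`, `mcmc`, `seed`.
#' @export
fit_growth <- function(data, priors = growth_priors(),
                       mcmc = mcmc_config(), seed = 1L, init = NULL) {
  increments <- if (inherits(data, "capture_dataset")) {
    build_growth_increments(data$events)
  } else data
  dat <- growth_model_data(increments)
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    growth_sample_chain(dat, priors, mcmc, chain_seed(seed, ch), init)
  })
  draws <- posterior_draws(chains)
  # R-hat over the structural parameters (not per-individual effects)
  core <- c("upsilon_f", "theta_m", "mu_f", "beta_m", "sigma_k_year",
            "sigma_k_site", "sigma_k_indiv", "sigma_a_site", "sigma_e",
            "mu_a_m", "mu_k_m")
  sub <- posterior_draws(lapply(draws$chains,
                                function(ch) ch[, core, drop = FALSE]))
  conv <- convergence_report(sub)
  structure(list(draws = draws, convergence = conv, model_data = dat,
                 priors = priors, mcmc = mcmc, seed = seed),
            class = "vb_growth_fit")
}

#' @export
print.vb_growth_fit <- function(x, ...) {
  cat("Hierarchical von Bertalanffy growth fit:",
      length(x$draws$chains), "chains x", nrow(x$draws$chains[[1]]),
      "draws;", x$model_data$n_inc, "increments from", x$model_data$n_ind,
      "individuals\n")
  cat("max split R-hat (core parameters):",
      round(x$convergence$max_rhat, 3),
      if (x$convergence$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

growth_init_state <- function(dat, init) {
  st <- list(
    upsilon_f = 700 + rnorm(1, 0, 30),
    theta_m = rnorm(1, -100, 40),
    mu_f = rnorm(1, 5, 0.5),
    beta_m = rnorm(1, 0, 0.3),
    eta = rnorm(length(dat$groups), 0, 5),
    alpha = rnorm(length(dat$groups), 0, 0.1),
    zeta = rnorm(length(dat$years), 0, 0.05),
    iota = rep(0, dat$n_ind),
    sigma_k_year = 0.2, sigma_k_site = 0.5, sigma_k_indiv = 0.4,
    sigma_a_site = 20, sigma_e = exp(log(20) + rnorm(1, 0, 0.2)),
    m = as.numeric(dat$sex == "male")
  )
  st$m[dat$unknown] <- rbinom(length(dat$unknown), 1, 0.5)
  if (!is.null(init)) st[names(init)] <- init
  st
}

growth_sample_chain <- function(dat, pr, mcmc, seed, init) {
  set.seed(seed %% .Machine$integer.max)
  st <- growth_init_state(dat, init)

  scalar_names <- c("upsilon_f", "theta_m", "mu_f", "beta_m")
  sigma_names <- c("sigma_k_year", "sigma_k_site", "sigma_k_indiv",
                   "sigma_a_site", "sigma_e")
  nG <- length(dat$groups); nY <- length(dat$years)
  n_scalar <- 4L + 5L + nG + nG + nY
  ad <- adapt_state(n_scalar, init_scale = 0.2)
  ad$log_scale[1:2] <- log(10)            # asymptote scale (mm)
  ad$log_scale[5:9] <- log(0.15)          # log-sigma scale
  ad_iota <- adapt_state(dat$n_ind, init_scale = 0.3)

  ll_vec <- growth_ll_vec(st, dat)
  lp <- growth_log_prior(st, pr)
  lp_iota <- growth_iota_prior_vec(st)

  # translation moves along likelihood-invariant ridges of the hierarchy:
  # shift a grand mean and subtract the shift from its random effects, so
  # the linear predictors (and the likelihood) are unchanged and only the
  # prior decides.  These are what let the intercepts decorrelate from
  # their effect vectors.
  male_cells <- grep("^male\\.", dat$groups)
  trans_moves <- list(
    function(st, d) { st$upsilon_f <- st$upsilon_f + d
                      st$eta <- st$eta - d; st },
    function(st, d) { st$theta_m <- st$theta_m + d
                      st$eta[male_cells] <- st$eta[male_cells] - d; st },
    function(st, d) { st$mu_f <- st$mu_f + d; st$alpha <- st$alpha - d; st },
    function(st, d) { st$beta_m <- st$beta_m + d
                      st$alpha[male_cells] <- st$alpha[male_cells] - d; st },
    function(st, d) { st$mu_f <- st$mu_f + d; st$zeta <- st$zeta - d; st },
    function(st, d) { st$mu_f <- st$mu_f + d; st$iota <- st$iota - d; st }
  )
  ad_tr <- adapt_state(length(trans_moves), init_scale = 1)
  ad_tr$log_scale <- log(c(10, 10, 0.3, 0.3, 0.1, 0.1))

  n_iter <- mcmc$warmup + mcmc$draws * mcmc$thin
  eta_lab <- paste0("eta[", dat$groups, "]")
  alpha_lab <- paste0("alpha[", dat$groups, "]")
  zeta_lab <- paste0("zeta[", dat$years, "]")
  iota_lab <- paste0("iota[", dat$ids, "]")
  m_lab <- if (length(dat$unknown)) paste0("male[", dat$ids[dat$unknown], "]")
           else character(0)
  cols <- c(scalar_names, sigma_names, eta_lab, alpha_lab, zeta_lab,
            iota_lab, m_lab, "mu_a_m", "mu_k_m")
  out <- matrix(NA_real_, mcmc$draws, length(cols),
                dimnames = list(NULL, cols))
  keep_row <- 0L

  for (iter in seq_len(n_iter)) {
    comp <- 0L
    # --- scalar fixed effects ---
    for (nm in scalar_names) {
      comp <- comp + 1L
      prop <- st
      prop[[nm]] <- st[[nm]] + exp(ad$log_scale[comp]) * rnorm(1)
      ll_new <- growth_ll_vec(prop, dat)
      lp_new <- growth_log_prior(prop, pr)
      acc <- log(runif(1)) < (sum(ll_new) + lp_new) - (sum(ll_vec) + lp)
      if (acc) { st <- prop; ll_vec <- ll_new; lp <- lp_new }
      ad <- adapt_record(ad, comp, acc)
    }
    # --- log-scale SD updates ---
    for (nm in sigma_names) {
      comp <- comp + 1L
      prop <- st
      prop[[nm]] <- st[[nm]] * exp(exp(ad$log_scale[comp]) * rnorm(1))
      ll_new <- if (nm == "sigma_e") growth_ll_vec(prop, dat) else ll_vec
      lp_new <- growth_log_prior(prop, pr)
      lpi_new <- if (nm == "sigma_k_indiv") growth_iota_prior_vec(prop)
                 else lp_iota
      acc <- log(runif(1)) < (sum(ll_new) + lp_new + sum(lpi_new)) -
                             (sum(ll_vec) + lp + sum(lp_iota))
      if (acc) { st <- prop; ll_vec <- ll_new; lp <- lp_new
                 lp_iota <- lpi_new }
      ad <- adapt_record(ad, comp, acc)
    }
    # --- grouped random effects, scalar updates ---
    for (block in list(list(field = "eta", n = nG),
                       list(field = "alpha", n = nG),
                       list(field = "zeta", n = nY))) {
      for (g in seq_len(block$n)) {
        comp <- comp + 1L
        prop <- st
        prop[[block$field]][g] <- st[[block$field]][g] +
          exp(ad$log_scale[comp]) * rnorm(1)
        ll_new <- growth_ll_vec(prop, dat)
        lp_new <- growth_log_prior(prop, pr)
        acc <- log(runif(1)) < (sum(ll_new) + lp_new) - (sum(ll_vec) + lp)
        if (acc) { st <- prop; ll_vec <- ll_new; lp <- lp_new }
        ad <- adapt_record(ad, comp, acc)
      }
    }
    # --- likelihood-invariant translation moves ---
    for (tm in seq_along(trans_moves)) {
      prop <- trans_moves[[tm]](st, exp(ad_tr$log_scale[tm]) * rnorm(1))
      lp_new <- growth_log_prior(prop, pr)
      lpi_new <- growth_iota_prior_vec(prop)
      acc <- log(runif(1)) < (lp_new + sum(lpi_new)) - (lp + sum(lp_iota))
      if (acc) { st <- prop; lp <- lp_new; lp_iota <- lpi_new }
      ad_tr <- adapt_record(ad_tr, tm, acc)
    }
    # --- individual effects: propose all, accept elementwise ---
    prop <- st
    prop$iota <- st$iota + exp(ad_iota$log_scale) * rnorm(dat$n_ind)
    ll_new <- growth_ll_vec(prop, dat)
    lpi_new <- growth_iota_prior_vec(prop)
    by_old <- rowsum_safe(ll_vec, dat$ind, dat$n_ind)
    by_new <- rowsum_safe(ll_new, dat$ind, dat$n_ind)
    acc_i <- log(runif(dat$n_ind)) < (by_new + lpi_new) - (by_old + lp_iota)
    st$iota[acc_i] <- prop$iota[acc_i]
    ad_iota$attempted <- ad_iota$attempted + 1
    ad_iota$accepted <- ad_iota$accepted + as.numeric(acc_i)
    ll_vec <- growth_ll_vec(st, dat)
    lp_iota <- growth_iota_prior_vec(st)
    # --- latent sex for unknown-sex individuals (Gibbs) ---
    if (length(dat$unknown)) {
      st0 <- st; st0$m[dat$unknown] <- 0
      st1 <- st; st1$m[dat$unknown] <- 1
      by0 <- rowsum_safe(growth_ll_vec(st0, dat), dat$ind, dat$n_ind)
      by1 <- rowsum_safe(growth_ll_vec(st1, dat), dat$ind, dat$n_ind)
      for (u in dat$unknown) {
        pm <- 1 / (1 + exp(by0[u] - by1[u]))  # Bernoulli(0.5) prior cancels
        st$m[u] <- rbinom(1, 1, pm)
      }
      ll_vec <- growth_ll_vec(st, dat)
    }

    ad <- adapt_maybe_update(ad, iter, mcmc$warmup)
    ad_iota <- adapt_maybe_update(ad_iota, iter, mcmc$warmup)
    ad_tr <- adapt_maybe_update(ad_tr, iter, mcmc$warmup)

    if (iter > mcmc$warmup &&
        (iter - mcmc$warmup) %% mcmc$thin == 0L) {
      keep_row <- keep_row + 1L
      out[keep_row, ] <- c(
        st$upsilon_f, st$theta_m, st$mu_f, st$beta_m,
        st$sigma_k_year, st$sigma_k_site, st$sigma_k_indiv,
        st$sigma_a_site, st$sigma_e,
        st$eta, st$alpha, st$zeta, st$iota, st$m[dat$unknown],
        st$upsilon_f + st$theta_m, st$mu_f + st$beta_m)
    }
  }
  out
}

rowsum_safe <- function(x, group, n) {
  out <- rep(0, n)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Expected lengths for every increment at one posterior draw (named vector).
growth_expected_at <- function(drawvec, dat) {
  st <- list(
    upsilon_f = drawvec[["upsilon_f"]], theta_m = drawvec[["theta_m"]],
    mu_f = drawvec[["mu_f"]], beta_m = drawvec[["beta_m"]],
    eta = unname(drawvec[paste0("eta[", dat$groups, "]")]),
    alpha = unname(drawvec[paste0("alpha[", dat$groups, "]")]),
    zeta = unname(drawvec[paste0("zeta[", dat$years, "]")]),
    iota = unname(drawvec[paste0("iota[", dat$ids, "]")]),
    m = as.numeric(dat$sex == "male")
  )
  if (length(dat$unknown)) {
    st$m[dat$unknown] <- unname(
      drawvec[paste0("male[", dat$ids[dat$unknown], "]")])
  }
  mu <- growth_mu_vec(st, dat)
  stop_if(is.null(mu), "draw implies an asymptote below a start length")
  mu
}

#' Project size at age from a fitted growth model
#'
#' For each posterior draw, draws a neonate length from `N(l0_mean, l0_sd)`
#' and projects the deterministic growth curve with that draw's sex-specific
#' mean asymptote and growth coefficient (site, year and individual effects
#' set to zero, i.e. an average site in an average year), then summarizes
#' across draws at each age.
#'
#' @param fit a `vb_growth_fit`.
#' @param sex `"female"` or `"male"`.
#' @param ages ascending vector of ages in years.
#' @param l0_mean,l0_sd neonate length distribution (mm); defaults 165 and
#'   10, typical of neonate gartersnakes.
#' @param seed RNG seed for the neonate draws.
#' @return data frame with `age`, `mean`, `median`, `lower`, `upper` (mm).
#' @export
project_size_at_age <- function(fit, sex = c("female", "male"), ages = 0:10,
                                l0_mean = 165, l0_sd = 10, seed = 1L) {
  sex <- match.arg(sex)
  stop_if(is.unsorted(ages, strictly = TRUE), "'ages' must be ascending")
  stop_if(any(ages < 0), "'ages' must be non-negative")
  dm <- draws_matrix(fit$draws)
  m <- as.numeric(sex == "male")
  a <- dm[, "upsilon_f"] + m * dm[, "theta_m"]
  k <- exp(dm[, "mu_f"] + m * dm[, "beta_m"])
  set.seed(as.integer(seed) %% .Machine$integer.max)
  l0 <- rnorm(length(a), l0_mean, l0_sd)
  proj <- vapply(ages, function(ag) a - (a - l0) * exp(-k * ag / a),
                 numeric(length(a)))
  data.frame(
    age = ages,
    mean = colMeans(proj),
    median = apply(proj, 2, median),
    lower = apply(proj, 2, quantile, 0.025),
    upper = apply(proj, 2, quantile, 0.975)
  )
}
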