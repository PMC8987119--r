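#' von Bertalanffy expected length
#'
#' Deterministic growth kernel used throughout the package.  Growth is
#' parameterized with the exponent `k / a` so that the growth coefficient and
#' the asymptote can vary independently between individuals:
#' \deqn{E[L_t] = a - (a - L_{t-1}) \exp(-(k/a)\,\Delta t).}
#'
#' @param l_prev previous length (mm).
#' @param a asymptotic length (mm); must be positive.
#' @param k growth coefficient (mm/yr); non-negative.
#' @param delta_years elapsed time in years; non-negative.
#'
#' @details All arguments recycle to a common length.  The kernel works in
#'   years; callers holding day counts divide by 365.25 first (see
#'   [build_growth_increments()]).  When `l_prev < a` the result lies strictly
#'   between `l_prev` and `a` for positive `k` and `delta_years`, and `a` is a
#'   fixed point.
#'
#' @return expected length (mm), same length as the recycled inputs.
#' @export
#' @examples
#' vb_expected_length(165, a = 737.23, k = exp(5.55), delta_years = 1)
vb_expected_length <- function(l_prev, a, k, delta_years) {
  stop_if(any(a <= 0), "asymptotic length 'a' must be positive")
  stop_if(any(k < 0), "growth coefficient 'k' must be non-negative")
  stop_if(any(delta_years < 0), "'delta_years' must be non-negative")
  a - (a - l_prev) * exp(-(k / a) * delta_years)
}

#' Compose von Bertalanffy growth across segments with different rates
#'
#' Applies [vb_expected_length()] sequentially over segments (e.g. calendar
#' years with year-specific growth coefficients).  Because the kernel is
#' exponential in `k * dt / a`, the composition equals the closed form
#' `a - (a - l_start) * exp(-sum(k * dt) / a)`.
#'
#' @param l_start starting length (mm).
#' @param a asymptotic length (mm).
#' @param k_per_segment vector of growth coefficients (mm/yr), one per segment.
#' @param dt_per_segment vector of segment durations (years), same length.
#'
#' @return length after traversing all segments (mm).
#' @export
vb_compose_segments <- function(l_start, a, k_per_segment, dt_per_segment) {
  stop_if(length(k_per_segment) != length(dt_per_segment),
          "'k_per_segment' and 'dt_per_segment' must have equal length")
  stop_if(any(dt_per_segment < 0), "segment durations must be non-negative")
  stop_if(any(a <= 0), "asymptotic length 'a' must be positive")
  if (length(k_per_segment) == 0L) return(l_start)
  a - (a - l_start) * exp(-sum(k_per_segment * dt_per_segment) / a)
}

#' Linear predictors of the hierarchical growth model
#'
#' Maps sex, site and year structure to an individual's asymptote and
#' year-specific log growth coefficients:
#' `a_i = upsilon_f + theta_m * m_i + eta[sex, site]` and
#' `log k_{i,t} = mu_f + beta_m * m_i + alpha[sex, site] + zeta_t + iota_i`.
#'
#' @param male 0/1 indicator of male sex.
#' @param eta sex-by-site random effect on the asymptote (mm) for this
#'   individual's sex-site cell.
#' @param alpha sex-by-site random effect on log k for this cell.
#' @param zeta vector of year random effects on log k (one per year of
#'   interest).
#' @param iota individual random effect on log k.
#' @param params named list with elements `upsilon_f`, `theta_m`, `mu_f`,
#'   `beta_m`.
#'
#' @return list with `a` (scalar, mm) and `log_k` (vector over `zeta`).
#' @export
growth_linear_predictors <- function(male, params, eta = 0, alpha = 0,
                                     zeta = 0, iota = 0) {
  a <- params$upsilon_f + params$theta_m * male + eta
  log_k <- params$mu_f + params$beta_m * male + alpha + zeta + iota
  list(a = a, log_k = log_k)
}

#' Log-likelihood of growth increments
#'
#' Each increment contributes a normal log density for the observed end
#' length around the von Bertalanffy expectation from its start length.
#' Increments spanning several calendar years are segmented at year
#' boundaries so that year-specific growth coefficients apply to the time
#' actually spent in each year.
#'
#' @param increments data frame as returned by [build_growth_increments()].
#' @param params list with `upsilon_f`, `theta_m`, `mu_f`, `beta_m`,
#'   `sigma_e`, and optionally per-increment effect lookups via the
#'   `effects` argument.
#' @param effects optional list of per-increment vectors `eta`, `alpha`,
#'   `iota`, `male` and a function or matrix giving `zeta` by year; by
#'   default all random effects are zero and `male` is taken from the
#'   increment's `sex` column (`"male"` = 1).
#'
#' @return total log-likelihood (scalar) with attribute `"per_increment"`.
#' @export
growth_log_likelihood <- function(increments, params, effects = list()) {
  stop_if(params$sigma_e <= 0, "'sigma_e' must be positive")
  n <- nrow(increments)
  male <- effects$male %||% as.numeric(increments$sex == "male")
  eta <- rep_len(effects$eta %||% 0, n)
  alpha <- rep_len(effects$alpha %||% 0, n)
  iota <- rep_len(effects$iota %||% 0, n)
  zeta_by_year <- effects$zeta_by_year  # named vector by calendar year

  per <- vapply(seq_len(n), function(j) {
    seg <- increment_year_segments(increments$start_date[j],
                                   increments$end_date[j])
    zeta <- if (is.null(zeta_by_year)) {
      rep(0, nrow(seg))
    } else {
      z <- zeta_by_year[as.character(seg$year)]
      z[is.na(z)] <- 0
      z
    }
    lp <- growth_linear_predictors(male[j], params, eta = eta[j],
                                   alpha = alpha[j], zeta = zeta,
                                   iota = iota[j])
    mu <- vb_compose_segments(increments$l_start_mm[j], lp$a,
                              exp(lp$log_k), seg$dt_years)
    dnorm(increments$l_end_mm[j], mu, params$sigma_e, log = TRUE)
  }, numeric(1))
  structure(sum(per), per_increment = per)
}

# Split the interval [start_date, end_date) at calendar-year boundaries.
# Returns data.frame(year, dt_years); dt_years sums to the full elapsed time.
increment_year_segments <- function(start_date, end_date) {
  stop_if(end_date < start_date, "end date precedes start date")
  y0 <- as.integer(format(start_date, "%Y"))
  y1 <- as.integer(format(end_date, "%Y"))
  years <- y0:y1
  bounds <- as.Date(paste0(c(years, y1 + 1L), "-01-01"))
  lo <- pmax(as.numeric(bounds[seq_along(years)]), as.numeric(start_date))
  hi <- pmin(as.numeric(bounds[seq_along(years) + 1L]), as.numeric(end_date))
  dt <- pmax(hi - lo, 0) / DAYS_PER_YEAR
  keep <- dt > 0 | length(years) == 1L
  data.frame(year = years[keep], dt_years = dt[keep])
}
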