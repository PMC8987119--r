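# Three-state robust-design CJS machinery: scalar linear predictors,
# transition/emission structure, and a readable single-history forward
# algorithm.  The production sampler uses a vectorized C++ version of the
# same recursion; tests check the two against each other and against
# brute-force enumeration over latent-state sequences.

#' Survival probability at a given size
#'
#' `logit(phi) = intercept + f_phi(svl) + xi_year`; the size smooth is shared
#' across sexes and sites (intercepts are not).
#'
#' @param svl standardized SVL.
#' @param intercept sex-site intercept on the logit scale.
#' @param smooth_coef list with `q`, `b` for the survival smooth (use `b = 0`
#'   and `q = 0` to switch the smooth off).
#' @param spec a [spline_spec()].
#' @param year_effect annual random effect on the logit scale.
#' @return survival probability.
#' @export
survival_logit <- function(svl, intercept, smooth_coef, spec,
                           year_effect = 0) {
  inv_logit(intercept +
              smooth_value(svl, spec, smooth_coef, standardized = TRUE) +
              year_effect)
}

#' Daily capture probability at a given size and survey conditions
#'
#' `logit(p) = intercept + delta' W + f_p(svl) + omega_site_year`, with `W`
#' the standardized occasion covariates (air temperature, relative humidity,
#' day of year, and the binary precipitation flag).
#'
#' @param svl standardized SVL.
#' @param intercept sex-site intercept (logit).
#' @param delta coefficient vector, one per covariate column.
#' @param covariates numeric vector (or matrix with rows as occasions) of
#'   standardized covariate values; must be complete.
#' @param smooth_coef,spec the capture-size smooth.
#' @param site_year_effect site-by-year random effect (logit).
#' @return capture probability (vector over occasions when `covariates` is a
#'   matrix).
#' @export
capture_logit <- function(svl, intercept, delta, covariates, smooth_coef,
                          spec, site_year_effect = 0) {
  W <- if (is.matrix(covariates)) covariates else matrix(covariates, 1)
  stop_if(anyNA(W), "missing survey covariate")
  stop_if(ncol(W) != length(delta), "covariate/coefficient length mismatch")
  inv_logit(intercept + drop(W %*% delta) +
              smooth_value(svl, spec, smooth_coef, standardized = TRUE) +
              site_year_effect)
}

#' Availability for capture at a given size
#'
#' `logit(gamma) = intercept + lambda * svl + nu_site_year`: a linear size
#' effect (no spline), increasing in size when `lambda > 0`.
#'
#' @param svl standardized SVL.
#' @param intercept sex-site intercept (logit).
#' @param lambda slope of availability against standardized SVL.
#' @param site_year_effect site-by-year random effect (logit).
#' @return availability probability.
#' @export
availability_logit <- function(svl, intercept, lambda,
                               site_year_effect = 0) {
  inv_logit(intercept + lambda * svl + site_year_effect)
}

#' Transition matrix of the three-state random-emigration model
#'
#' States: 1 available, 2 temporarily unavailable, 3 dead or permanently
#' emigrated.  Under random emigration the availability of a survivor does
#' not depend on the previous state, so rows 1 and 2 are identical; death is
#' absorbing.
#'
#' @param phi apparent survival probability for the interval.
#' @param gamma availability probability in the destination primary period.
#' @return 3 x 3 row-stochastic matrix.
#' @export
transition_matrix <- function(phi, gamma) {
  stop_if(phi < 0 || phi > 1 || gamma < 0 || gamma > 1,
          "'phi' and 'gamma' must lie in [0, 1]")
  alive_row <- c(phi * gamma, phi * (1 - gamma), 1 - phi)
  rbind(available = alive_row, unavailable = alive_row,
        dead = c(0, 0, 1))
}

#' Emission probability of a within-primary detection vector
#'
#' An available individual yields independent Bernoulli detections with the
#' per-occasion capture probabilities; an unavailable or dead individual
#' cannot be detected, so any detection has probability zero and an all-zero
#' history has probability one.  The latter implements the known-available
#' rule: occasions on which an individual was not available contribute no
#' information about `p`.
#'
#' @param state one of `"available"`, `"unavailable"`, `"dead"`.
#' @param detections binary vector over the primary period's occasions.
#' @param p per-occasion capture probabilities, same length.
#' @return probability of the detection vector given the state.
#' @export
emission_probability <- function(state, detections, p) {
  stop_if(length(detections) != length(p),
          "detections and p must have equal length")
  state <- match.arg(state, c("available", "unavailable", "dead"))
  if (state == "available") {
    return(prod(ifelse(detections == 1, p, 1 - p)))
  }
  if (any(detections == 1)) 0 else 1
}

#' Forward-algorithm log-likelihood of one capture history
#'
#' Computes the marginal probability of a robust-design capture history by
#' the forward algorithm over the three latent states, conditioning on first
#' capture: the individual is available with probability one in its
#' first-capture primary period, occasions before the first detection
#' contribute nothing, and occasions after it contribute Bernoulli terms.
#'
#' @param detections list of binary vectors, one per primary period from the
#'   first-capture primary onward; the first vector must contain at least
#'   one detection (the initial capture).
#' @param p list of per-occasion capture probability vectors matching
#'   `detections`.
#' @param phi survival probabilities per interval (length: primaries - 1).
#' @param gamma availability probabilities per primary period from the
#'   second onward (length: primaries - 1).
#' @return log-likelihood of the history.
#' @export
history_log_likelihood <- function(detections, p, phi, gamma) {
  T_len <- length(detections)
  stop_if(length(p) != T_len, "detections and p must have equal length")
  stop_if(length(phi) != max(T_len - 1, 0) ||
            length(gamma) != max(T_len - 1, 0),
          "phi and gamma must have one entry per interval")
  first_det <- which(detections[[1]] == 1)
  stop_if(length(first_det) == 0,
          "history must begin with the first-capture primary period")
  # occasions after the initial capture in the release primary
  j0 <- first_det[1]
  keep <- seq_along(detections[[1]]) > j0
  f <- c(available = emission_probability("available",
                                          detections[[1]][keep],
                                          p[[1]][keep]),
         unavailable = 0, dead = 0)
  if (T_len > 1) {
    for (t in 2:T_len) {
      tm <- transition_matrix(phi[t - 1], gamma[t - 1])
      f <- drop(f %*% tm)
      e <- vapply(c("available", "unavailable", "dead"),
                  emission_probability, numeric(1),
                  detections = detections[[t]], p = p[[t]])
      f <- f * e
    }
  }
  log(sum(f))
}

#' Propagate latent size across primary periods
#'
#' Deterministic size trajectory given growth parameters: starting from the
#' (observed or imputed) first-capture SVL, the von Bertalanffy kernel is
#' applied between consecutive primary-period midpoints, using the growth
#' coefficient of the calendar year in which each interval starts.  Observed
#' remeasurements enter the joint likelihood as normal deviates around these
#' latent sizes.
#'
#' @param first_svl SVL at the first-capture primary (mm).
#' @param a asymptotic length for this individual (mm).
#' @param k_by_year named vector of growth coefficients (mm/yr) by calendar
#'   year.
#' @param primary_dates Date vector of primary-period midpoints, ascending,
#'   the first being the first-capture primary.
#' @return vector of latent SVLs, one per primary period.
#' @export
propagate_latent_size <- function(first_svl, a, k_by_year, primary_dates) {
  n <- length(primary_dates)
  out <- numeric(n)
  out[1] <- first_svl
  if (n > 1) {
    for (t in 2:n) {
      dt <- as.numeric(primary_dates[t] - primary_dates[t - 1]) /
        DAYS_PER_YEAR
      yr <- format(primary_dates[t - 1], "%Y")
      k <- if (yr %in% names(k_by_year)) k_by_year[[yr]] else
        stop("no growth coefficient for year ", yr, call. = FALSE)
      out[t] <- vb_expected_length(out[t - 1], a, k, dt)
    }
  }
  out
}

#' Latent-input specification for missing sizes and sexes
#'
#' Identifies which individuals need latent nodes in the joint model:
#' individuals not measured at first capture get a latent initial SVL with a
#' normal prior using the mean and SD of measured first-capture SVLs of
#' their sex (unknown-sex individuals use all measured individuals), and
#' unknown-sex individuals get a latent male indicator with a
#' Bernoulli(0.5) prior shared across the growth and CMR blocks.
#'
#' @param individuals individuals table (from [read_captures()] or a
#'   `capture_dataset`).
#' @return list with `latent_svl` (data frame: id, prior_mean, prior_sd) and
#'   `latent_sex` (ids).
#' @export
impute_missing_inputs <- function(individuals) {
  if (inherits(individuals, "capture_dataset")) {
    individuals <- individuals$individuals
  }
  measured <- individuals[!is.na(individuals$first_svl_mm), , drop = FALSE]
  sex_stats <- lapply(c("female", "male"), function(s) {
    v <- measured$first_svl_mm[measured$sex == s]
    stop_if(length(v) < 2L, "no measured first-capture SVL for sex '", s,
            "'; cannot build an imputation prior")
    c(mean = mean(v), sd = sd(v))
  })
  names(sex_stats) <- c("female", "male")
  all_stats <- c(mean = mean(measured$first_svl_mm),
                 sd = sd(measured$first_svl_mm))
  need <- individuals[is.na(individuals$first_svl_mm), , drop = FALSE]
  latent_svl <- data.frame(
    id = need$id,
    prior_mean = vapply(need$sex, function(s) {
      if (s %in% names(sex_stats)) sex_stats[[s]][["mean"]]
      else all_stats[["mean"]]
    }, numeric(1)),
    prior_sd = vapply(need$sex, function(s) {
      if (s %in% names(sex_stats)) sex_stats[[s]][["sd"]]
      else all_stats[["sd"]]
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(latent_svl) <- NULL
  list(latent_svl = latent_svl,
       latent_sex = individuals$id[individuals$sex == "unknown"],
       sex_stats = sex_stats)
}
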