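#' Residual sum of squares discrepancy
#'
#' Goodness-of-fit discrepancy for the growth model: the sum of squared
#' differences between observed and expected lengths.
#'
#' @param observed,expected paired numeric vectors.
#' @return scalar sum of squares.
#' @export
growth_ssr <- function(observed, expected) {
  stop_if(length(observed) != length(expected),
          "observed and expected must have equal length")
  sum((observed - expected)^2)
}

#' Freeman–Tukey discrepancy
#'
#' Variance-stabilized discrepancy for count data:
#' `sum((sqrt(observed) - sqrt(expected))^2)`.
#'
#' @param observed,expected paired nonnegative vectors.
#' @return scalar discrepancy.
#' @export
freeman_tukey <- function(observed, expected) {
  stop_if(length(observed) != length(expected),
          "observed and expected must have equal length")
  stop_if(any(observed < 0) || any(expected < 0),
          "Freeman-Tukey inputs must be nonnegative")
  sum((sqrt(observed) - sqrt(expected))^2)
}

#' Bayesian p-value from a discrepancy pair
#'
#' Fraction of posterior draws in which the replicate-data discrepancy meets
#' or exceeds the observed-data discrepancy (ties count toward the event).
#' Values near 0 or 1 indicate misfit; a well-calibrated model on its own
#' data gives values away from both extremes.
#'
#' @param t_observed discrepancy of the real data, one value per draw.
#' @param t_replicate discrepancy of data replicated from the same draw.
#' @return scalar p-value.
#' @export
bayesian_p_value <- function(t_observed, t_replicate) {
  stop_if(length(t_observed) != length(t_replicate),
          "discrepancy vectors must have equal length")
  stop_if(length(t_observed) == 0L, "empty discrepancy pair")
  mean(t_replicate >= t_observed)
}

#' Posterior predictive check for the growth model
#'
#' For each posterior draw, computes expected lengths for every increment at
#' that draw's parameters, the residual sum of squares of the observed end
#' lengths, and the same statistic for end lengths re-simulated from the
#' model at that draw.
#'
#' @param fit a `vb_growth_fit` from [fit_growth()].
#' @param n_draws number of posterior draws to use (default 500, thinned
#'   evenly across the chains).
#' @param seed RNG seed for the replicate data.
#' @return list with `t_observed`, `t_replicate` (per used draw) and
#'   `p_value`.
#' @export
ppc_growth <- function(fit, n_draws = 500L, seed = 1L) {
  dm <- draws_matrix(fit$draws)
  use <- unique(round(seq(1, nrow(dm), length.out = min(n_draws, nrow(dm)))))
  dat <- fit$model_data
  set.seed(as.integer(seed) %% .Machine$integer.max)
  t_obs <- t_rep <- numeric(length(use))
  for (s in seq_along(use)) {
    mu <- growth_expected_at(dm[use[s], ], dat)
    sigma_e <- dm[use[s], "sigma_e"]
    t_obs[s] <- growth_ssr(dat$l_end, mu)
    l_rep <- rnorm(length(mu), mu, sigma_e)
    t_rep[s] <- growth_ssr(l_rep, mu)
  }
  list(t_observed = t_obs, t_replicate = t_rep,
       p_value = bayesian_p_value(t_obs, t_rep))
}

#' Posterior predictive check for the robust-design model
#'
#' Uses within-primary recapture counts per individual and primary period as
#' the checked statistic.  Expected counts are `Pr(available) * (1 - prod(1 -
#' p_j))`; availability can be conditioned on the individual's detection
#' history through the forward filter (`mode = "conditional"`) or taken from
#' the unconditional state distribution implied by the transition chain
#' (`mode = "marginal"`).  Replicate counts are simulated from the same draw
#' by evolving states and detections generatively.  Discrepancies are
#' Freeman–Tukey on the counts.
#'
#' @param fit a `vb_cmr_fit` from [fit_cmr()].
#' @param n_draws number of posterior draws to use (default 300).
#' @param mode `"conditional"` (default) or `"marginal"` availability.
#' @param seed RNG seed for the replicate data.
#' @return list with `t_observed`, `t_replicate` and `p_value`.
#' @export
ppc_cmr <- function(fit, n_draws = 300L, mode = c("conditional", "marginal"),
                    seed = 1L) {
  mode <- match.arg(mode)
  dm <- draws_matrix(fit$draws)
  use <- unique(round(seq(1, nrow(dm), length.out = min(n_draws, nrow(dm)))))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  t_obs <- t_rep <- numeric(length(use))
  for (s in seq_along(use)) {
    ft <- cmr_ppc_one_draw(dm[use[s], ], fit, mode)
    t_obs[s] <- ft$t_obs
    t_rep[s] <- ft$t_rep
  }
  list(t_observed = t_obs, t_replicate = t_rep,
       p_value = bayesian_p_value(t_obs, t_rep))
}
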