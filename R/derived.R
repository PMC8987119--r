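#' Annualized recapture probability
#'
#' Converts draws of a daily capture probability into draws of the
#' probability of being captured at least once over `n_days` secondary
#' occasions: `p* = 1 - (1 - p)^n_days`.  The transformation is applied per
#' draw, never to a posterior summary, so summaries of `p*` are correct under
#' the nonlinear map.
#'
#' @param p_daily_draws draws of daily capture probability, in `[0, 1]`.
#' @param n_days number of secondary occasions in a primary period
#'   (default 52, a typical season-long survey effort).
#' @return draws of `p*`, same length as `p_daily_draws`.
#' @export
annual_recapture_prob <- function(p_daily_draws, n_days = 52L) {
  stop_if(n_days < 1, "'n_days' must be >= 1")
  stop_if(any(p_daily_draws < 0 | p_daily_draws > 1),
          "daily capture probabilities must lie in [0, 1]")
  1 - (1 - p_daily_draws)^n_days
}

#' Posterior exceedance probability
#'
#' Fraction of paired draws in which `a` strictly exceeds `b`.
#'
#' @param draws_a,draws_b equal-length draw vectors, paired by draw.
#' @return scalar probability.
#' @export
prob_greater <- function(draws_a, draws_b) {
  stop_if(length(draws_a) != length(draws_b),
          "draw vectors must have equal length")
  stop_if(length(draws_a) == 0L, "empty draw vectors")
  mean(draws_a > draws_b)
}

#' Demographic rate as a function of body size
#'
#' Evaluates the survival, capture, or availability linear predictor over a
#' grid of SVL values for each posterior draw of a fitted robust-design
#' model (year effects set to zero), inverse-logit transforms draw by draw,
#' and then summarizes, returning the posterior mean, median and central 95%
#' band per grid point.
#'
#' @param fit a `vb_cmr_fit` from [fit_cmr()].
#' @param which one of `"survival"`, `"capture"`, `"availability"`.
#' @param svl_grid SVL values (mm).
#' @param sex `"female"` or `"male"`.
#' @param site site identifier present in the fit.
#' @param extrapolation_window how far (in standardized SVL units) outside
#'   the observed range grid points may lie before a warning (default 0.5).
#' @return data frame with `svl_mm`, `mean`, `median`, `lower`, `upper`.
#' @export
curve_vs_svl <- function(fit, which = c("survival", "capture",
                                        "availability"),
                         svl_grid, sex, site,
                         extrapolation_window = 0.5) {
  which <- match.arg(which)
  spec <- fit$spline_spec
  z <- std_apply(svl_grid, spec)
  if (any(z < spec$range[1] - extrapolation_window |
          z > spec$range[2] + extrapolation_window)) {
    warning("SVL grid extends beyond the observed size range; ",
            "curve is extrapolated there", call. = FALSE)
  }
  ss <- paste(sex, site, sep = ".")
  stop_if(!ss %in% fit$sex_site_levels, "no sex-site cell '", ss,
          "' in the fitted model")
  dm <- draws_matrix(fit$draws)
  n <- nrow(dm)
  lin <- switch(which,
    survival = {
      B <- spline_basis(z, spec, standardized = TRUE)
      qb <- dm[, c("q_phi", paste0("b_phi[", seq_len(spec$n_knots), "]")),
               drop = FALSE]
      dm[, paste0("pi_phi[", ss, "]")] + tcrossprod(qb, B)
    },
    capture = {
      B <- spline_basis(z, spec, standardized = TRUE)
      qb <- dm[, c("q_p", paste0("b_p[", seq_len(spec$n_knots), "]")),
               drop = FALSE]
      dm[, paste0("o_p[", ss, "]")] + tcrossprod(qb, B)
    },
    availability = {
      dm[, paste0("zeta_gamma[", ss, "]")] +
        tcrossprod(dm[, "lambda_gamma", drop = FALSE], cbind(z))
    })
  prob <- inv_logit(lin)  # n draws x grid
  data.frame(
    svl_mm = svl_grid,
    mean = colMeans(prob),
    median = apply(prob, 2, median),
    lower = apply(prob, 2, quantile, 0.025),
    upper = apply(prob, 2, quantile, 0.975)
  )
}
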