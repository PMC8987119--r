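#' Place spline knots at empirical quantiles
#'
#' Knot `g` (of `G`) sits at the empirical quantile of the covariate sample at
#' probability `g / (G + 1)`, using linear-interpolation quantiles
#' (`stats::quantile` type 7).  Knot placement depends only on the data, never
#' on model parameters, and knots are frozen before any model fitting.
#'
#' @param x_values observed covariate sample (e.g. measured SVLs).
#' @param n_knots number of interior knots `G` (default 5).
#'
#' @return numeric vector of `G` strictly ascending knots.
#' @export
place_knots <- function(x_values, n_knots = 5L) {
  x_values <- x_values[!is.na(x_values)]
  stop_if(n_knots < 1L, "'n_knots' must be >= 1")
  stop_if(length(unique(x_values)) < n_knots + 1L,
          "need more distinct covariate values than knots")
  probs <- seq_len(n_knots) / (n_knots + 1)
  kn <- unname(quantile(x_values, probs = probs, type = 7))
  stop_if(any(diff(kn) <= 0),
          "quantile knots are not strictly ascending; too few distinct values")
  kn
}

#' Specification of one penalized truncated-power smooth
#'
#' Builds the fixed part of a low-rank penalized spline: the covariate is
#' centered and scaled (for numerical stability of the cubic terms), knots are
#' placed at quantiles of the standardized sample, and the degree is stored.
#' The returned object is all that is needed to evaluate the basis anywhere.
#'
#' @param x_values observed covariate sample on the raw scale.
#' @param n_knots number of knots `G` (default 5).
#' @param degree polynomial degree `d` of the truncated-power terms
#'   (default 3).
#'
#' @return object of class `spline_spec` with fields `knots` (standardized
#'   scale), `degree`, `center`, `scale`, `n_knots`, `range` (standardized
#'   range of the sample).
#' @export
spline_spec <- function(x_values, n_knots = 5L, degree = 3L) {
  x_values <- x_values[!is.na(x_values)]
  std <- standardizer(x_values)
  z <- std_apply(x_values, std)
  structure(list(
    n_knots = as.integer(n_knots),
    degree = as.integer(degree),
    knots = place_knots(z, n_knots),
    center = std$center,
    scale = std$scale,
    range = range(z)
  ), class = "spline_spec")
}

#' Evaluate the truncated-power basis at covariate values
#'
#' Returns the design matrix `[x, (x - kappa_1)_+^d, ..., (x - kappa_G)_+^d]`
#' on the standardized scale.
#'
#' @param x covariate values; raw scale unless `standardized = TRUE`.
#' @param spec a [spline_spec()].
#' @param standardized set `TRUE` when `x` is already standardized.
#'
#' @return matrix with `length(x)` rows and `1 + G` columns.
#' @export
spline_basis <- function(x, spec, standardized = FALSE) {
  z <- if (standardized) x else std_apply(x, spec)
  tp <- outer(z, spec$knots, function(zz, kk) pmax(0, zz - kk)^spec$degree)
  cbind(linear = z, tp, deparse.level = 0)
}

#' Evaluate a penalized smooth at covariate values
#'
#' Computes `f(x) = q * x + sum_g b_g (x - kappa_g)_+^d` on the standardized
#' scale: the dot product of the basis row with the coefficients.
#'
#' @param x covariate values (raw scale unless `standardized = TRUE`).
#' @param spec a [spline_spec()].
#' @param coef list with `q` (scalar fixed slope) and `b` (vector of `G`
#'   penalized coefficients).
#' @param standardized set `TRUE` when `x` is already standardized.
#'
#' @return numeric vector of smooth contributions to a linear predictor.
#' @export
smooth_value <- function(x, spec, coef, standardized = FALSE) {
  stop_if(length(coef$b) != spec$n_knots,
          "coefficient vector 'b' must have one entry per knot")
  stop_if(length(coef$q) != 1L, "'q' must be a scalar")
  drop(spline_basis(x, spec, standardized) %*% c(coef$q, coef$b))
}
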