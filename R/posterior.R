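#' Labeled MCMC draws with chain structure
#'
#' Container for posterior samples: a list of per-chain matrices (iterations
#' by parameters) with identical dimensions and column labels.
#'
#' @param chains list of numeric matrices, one per chain, equal dimensions
#'   and identical column names.
#' @return object of class `posterior_draws`.
#' @export
posterior_draws <- function(chains) {
  stop_if(length(chains) < 1L, "need at least one chain")
  labs <- colnames(chains[[1]])
  stop_if(is.null(labs) || anyDuplicated(labs) > 0,
          "chains must have unique column labels")
  same <- vapply(chains, function(ch) {
    identical(dim(ch), dim(chains[[1]])) && identical(colnames(ch), labs)
  }, logical(1))
  stop_if(!all(same), "all chains must share dimensions and labels")
  structure(list(chains = lapply(chains, as.matrix), parameters = labs),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", length(x$chains), "chain(s) x",
      nrow(x$chains[[1]]), "draws,", length(x$parameters), "parameters\n")
  invisible(x)
}

#' @export
as.data.frame.posterior_draws <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$chains), function(c) {
    ch <- x$chains[[c]]
    data.frame(parameter = rep(colnames(ch), each = nrow(ch)),
               chain = c, draw = rep(seq_len(nrow(ch)), ncol(ch)),
               value = as.vector(ch), stringsAsFactors = FALSE)
  }))
}

#' Extract stacked draws of one parameter
#'
#' @param x a [posterior_draws()] object.
#' @param label parameter label.
#' @return numeric vector, chains concatenated in order.
#' @export
draws_of <- function(x, label) {
  stop_if(!label %in% x$parameters, "unknown parameter label '", label, "'")
  unlist(lapply(x$chains, function(ch) ch[, label]), use.names = FALSE)
}

#' All draws as one matrix
#'
#' @param x a [posterior_draws()] object.
#' @return matrix with chains stacked row-wise.
#' @export
draws_matrix <- function(x) do.call(rbind, x$chains)

#' Serialize draws to a columnar CSV
#'
#' Writes the long format (parameter, chain, draw, value); [read_draws()]
#' restores the `posterior_draws` object.
#'
#' @param x a [posterior_draws()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  labs <- unique(long$parameter)
  chains <- lapply(sort(unique(long$chain)), function(c) {
    sub <- long[long$chain == c, ]
    m <- vapply(labs, function(p) sub$value[sub$parameter == p],
                numeric(sum(long$chain == c) / length(labs)))
    colnames(m) <- labs
    m
  })
  posterior_draws(chains)
}

#' Posterior summary table
#'
#' Mean, SD and central 95% interval per parameter, in the order requested.
#'
#' @param x a [posterior_draws()] object.
#' @param labels parameters to summarize (default: all, in storage order).
#' @return data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`.
#' @export
summary_table <- function(x, labels = NULL) {
  labels <- labels %||% x$parameters
  unknown <- setdiff(labels, x$parameters)
  stop_if(length(unknown) > 0, "unknown parameter label(s): ",
          paste(unknown, collapse = ", "))
  rows <- lapply(labels, function(p) {
    d <- draws_of(x, p)
    data.frame(parameter = p, mean = mean(d), sd = sd(d),
               q2.5 = unname(quantile(d, 0.025, type = 7)),
               q97.5 = unname(quantile(d, 0.975, type = 7)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Potential scale reduction factor (split-chain R-hat)
#'
#' The Brooks–Gelman–Rubin statistic computed after splitting each chain in
#' half, so within-chain trends register as apparent non-convergence.
#'
#' @param x a [posterior_draws()] object, or a list/matrix of chains for a
#'   single parameter.
#' @param split split each chain in half first (default `TRUE`).
#' @return named vector of R-hat values (NA where within-chain variance is
#'   zero, flagged as undefined).
#' @export
rhat <- function(x, split = TRUE) {
  if (inherits(x, "posterior_draws")) {
    vals <- vapply(x$parameters, function(p) {
      rhat_one(lapply(x$chains, function(ch) ch[, p]), split = split)
    }, numeric(1))
    return(vals)
  }
  if (is.matrix(x)) x <- lapply(seq_len(ncol(x)), function(j) x[, j])
  rhat_one(x, split = split)
}

rhat_one <- function(chains, split = TRUE) {
  stop_if(length(chains) < 2L && !split, "need at least two chains")
  if (split) {
    chains <- unlist(lapply(chains, function(ch) {
      n <- length(ch)
      stop_if(n < 4L, "need at least 4 draws per chain for split R-hat")
      h <- floor(n / 2)
      list(ch[seq_len(h)], ch[seq.int(n - h + 1L, n)])
    }), recursive = FALSE)
  }
  n <- length(chains[[1]])
  m <- length(chains)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- n * var(means)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Convergence report
#'
#' @param x a [posterior_draws()] object.
#' @param threshold R-hat above which a parameter is flagged (default 1.05).
#' @return list with `rhat`, `max_rhat`, `flagged` labels and `converged`.
#' @export
convergence_report <- function(x, threshold = 1.05) {
  r <- rhat(x)
  flagged <- names(r)[!is.na(r) & r > threshold]
  list(rhat = r, max_rhat = suppressWarnings(max(r, na.rm = TRUE)),
       flagged = flagged, converged = length(flagged) == 0L,
       threshold = threshold)
}
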