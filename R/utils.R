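#' @useDynLib vbcmr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm dlogis plogis qlogis quantile rnorm runif rbinom
#'   rexp median sd var aggregate complete.cases setNames lm coef
#' @importFrom utils read.csv write.csv head
NULL

DAYS_PER_YEAR <- 365.25

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# days between two Date vectors, as integer
days_between <- function(start, end) {
  as.integer(round(as.numeric(difftime(end, start, units = "days"))))
}

# strict ISO-8601 date parsing; returns Date, NA where unparseable
parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  d <- as.Date(x, format = "%Y-%m-%d", optional = TRUE)
  # as.Date accepts impossible dates like 2014-02-29 by rolling in some locales;
  # round-trip to be strict
  bad <- !is.na(d) & format(d, "%Y-%m-%d") != x
  d[bad] <- NA
  d
}

# normalize sex labels to "female"/"male"/"unknown"
normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female")] <- "female"
  out[x %in% c("m", "male")] <- "male"
  out[is.na(x) | x == ""] <- "unknown"
  out
}

# standardization constants; returns list(center, scale)
standardizer <- function(x) {
  x <- x[!is.na(x)]
  stop_if(length(x) < 2L, "need at least two values to standardize")
  s <- sd(x)
  stop_if(s == 0, "cannot standardize a constant covariate")
  list(center = mean(x), scale = s)
}

std_apply <- function(x, std) (x - std$center) / std$scale
std_invert <- function(z, std) z * std$scale + std$center
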