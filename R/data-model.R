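#' Read capture records
#'
#' Reads a comma-separated capture table with columns `individual_id`, `site`,
#' `date` (ISO-8601), `sex`, `svl_mm`, `mass_g` (missing values as empty
#' cells).  Builds one individual per distinct id, with sex normalized to
#' female/male/unknown and the first capture date and first measured length
#' attached.
#'
#' @param path path to a captures CSV.
#' @return list with `events` (one row per capture, sorted by id then date)
#'   and `individuals` (one row per id).
#' @export
read_captures <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("individual_id", "site", "date", "sex", "svl_mm", "mass_g")
  miss <- setdiff(need, names(raw))
  stop_if(length(miss) > 0, "captures file is missing column(s): ",
          paste(miss, collapse = ", "))
  date <- parse_iso_date(raw$date)
  if (anyNA(date)) {
    bad <- which(is.na(date))[1]
    stop("unparseable date '", raw$date[bad], "' in captures row ", bad,
         call. = FALSE)
  }
  dup <- duplicated(raw[c("individual_id", "date")])
  if (any(dup)) {
    bad <- which(dup)[1]
    stop("duplicate capture of individual '", raw$individual_id[bad],
         "' on ", raw$date[bad], " (row ", bad, ")", call. = FALSE)
  }
  svl <- suppressWarnings(as.numeric(raw$svl_mm))
  svl[!nzchar(trimws(raw$svl_mm))] <- NA
  stop_if(any(!is.na(svl) & (svl <= 0 | svl >= 1000)),
          "svl_mm values must lie in (0, 1000) mm")
  mass <- suppressWarnings(as.numeric(raw$mass_g))
  mass[!nzchar(trimws(raw$mass_g))] <- NA

  events <- data.frame(
    individual_id = raw$individual_id,
    site = raw$site,
    date = date,
    sex = normalize_sex(raw$sex),
    svl_mm = svl,
    mass_g = mass,
    stringsAsFactors = FALSE
  )
  events <- events[order(events$individual_id, events$date), , drop = FALSE]
  rownames(events) <- NULL

  # sex should be constant per individual; resolve to the non-unknown value
  individuals <- do.call(rbind, lapply(split(events, events$individual_id),
    function(ev) {
      sexes <- setdiff(unique(ev$sex), "unknown")
      stop_if(length(sexes) > 1, "conflicting sex records for individual '",
              ev$individual_id[1], "'")
      first_svl <- ev$svl_mm[1]
      data.frame(
        id = ev$individual_id[1],
        sex = if (length(sexes) == 1) sexes else "unknown",
        site = ev$site[1],
        first_capture_date = ev$date[1],
        first_svl_mm = first_svl,
        stringsAsFactors = FALSE
      )
    }))
  rownames(individuals) <- NULL
  list(events = events, individuals = individuals)
}

#' Write capture records
#'
#' Inverse of [read_captures()]: emits the same CSV schema, with missing
#' values as empty cells, so a write/read round trip reproduces the events
#' table field-for-field.
#'
#' @param events capture events data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_captures <- function(events, path) {
  out <- data.frame(
    individual_id = events$individual_id,
    site = events$site,
    date = format(events$date, "%Y-%m-%d"),
    sex = events$sex,
    svl_mm = ifelse(is.na(events$svl_mm), "", format_num(events$svl_mm)),
    mass_g = ifelse(is.na(events$mass_g), "", format_num(events$mass_g)),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
  out
}

#' Read survey occasions
#'
#' Reads a comma-separated survey table with columns `site`, `date`,
#' `air_temp_c`, `rel_humidity_pct`, `precip_24h` (and optionally
#' `effort_traps`).  Assigns `primary_index` by calendar-year rank within
#' site, `secondary_index` by date rank within site-year, and computes
#' `day_of_year`.  Covariates must be complete; imputation of weather data is
#' out of scope.
#'
#' @param path path to a surveys CSV.
#' @return data frame of survey occasions.
#' @export
read_surveys <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("site", "date", "air_temp_c", "rel_humidity_pct", "precip_24h")
  miss <- setdiff(need, names(raw))
  stop_if(length(miss) > 0, "surveys file is missing column(s): ",
          paste(miss, collapse = ", "))
  date <- parse_iso_date(raw$date)
  if (anyNA(date)) {
    bad <- which(is.na(date))[1]
    stop("unparseable date '", raw$date[bad], "' in surveys row ", bad,
         call. = FALSE)
  }
  dup <- duplicated(raw[c("site", "date")])
  stop_if(any(dup), "duplicate (site, date) survey occasion at row ",
          which(dup)[1])
  covs <- lapply(raw[c("air_temp_c", "rel_humidity_pct", "precip_24h")],
                 function(v) suppressWarnings(as.numeric(v)))
  if (anyNA(covs$air_temp_c) || anyNA(covs$rel_humidity_pct) ||
      anyNA(covs$precip_24h)) {
    stop("missing survey covariate value; covariate imputation is out of ",
         "scope, surveys must be complete", call. = FALSE)
  }
  stop_if(!all(covs$precip_24h %in% c(0, 1)), "'precip_24h' must be 0/1")

  occ <- data.frame(
    site = raw$site,
    date = date,
    air_temp_c = covs$air_temp_c,
    rel_humidity_pct = covs$rel_humidity_pct,
    precip_24h = as.integer(covs$precip_24h),
    stringsAsFactors = FALSE
  )
  if ("effort_traps" %in% names(raw)) {
    occ$effort_traps <- suppressWarnings(as.numeric(raw$effort_traps))
  }
  occ <- occ[order(occ$site, occ$date), , drop = FALSE]
  occ$year <- as.integer(format(occ$date, "%Y"))
  occ$day_of_year <- as.integer(format(occ$date, "%j"))
  occ$primary_index <- NA_integer_
  occ$secondary_index <- NA_integer_
  for (s in unique(occ$site)) {
    sel <- occ$site == s
    occ$primary_index[sel] <- match(occ$year[sel], sort(unique(occ$year[sel])))
    for (t in unique(occ$primary_index[sel])) {
      sel2 <- sel & occ$primary_index == t
      occ$secondary_index[sel2] <- rank(occ$date[sel2])
    }
  }
  rownames(occ) <- NULL
  occ
}

#' Write survey occasions
#'
#' @param surveys survey occasions data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(surveys, path) {
  out <- data.frame(
    site = surveys$site,
    date = format(surveys$date, "%Y-%m-%d"),
    air_temp_c = format_num(surveys$air_temp_c),
    rel_humidity_pct = format_num(surveys$rel_humidity_pct),
    precip_24h = surveys$precip_24h,
    stringsAsFactors = FALSE
  )
  if ("effort_traps" %in% names(surveys)) out$effort_traps <- surveys$effort_traps
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Build growth increments from measured captures
#'
#' An individual with `n` measured captures (SVL present) contributes `n - 1`
#' increments between consecutive measurements; individuals measured fewer
#' than twice contribute none.  Elapsed time is the integer day count between
#' the two capture dates, including any inactive season.
#'
#' @param events capture events data frame (as from [read_captures()]).
#' @param shrink_warn_sd apparent shrinkage beyond `3 * shrink_warn_sd` mm
#'   triggers a warning (shrinkage within measurement noise is expected);
#'   default 23.33 mm, a typical residual SD for snake SVL remeasurement.
#' @return data frame with one row per increment: `individual_id`, `sex`,
#'   `site`, `l_start_mm`, `l_end_mm`, `delta_days`, `start_date`, `end_date`.
#' @export
build_growth_increments <- function(events, shrink_warn_sd = 23.33) {
  measured <- events[!is.na(events$svl_mm), , drop = FALSE]
  measured <- measured[order(measured$individual_id, measured$date), ,
                       drop = FALSE]
  pieces <- lapply(split(measured, measured$individual_id), function(ev) {
    n <- nrow(ev)
    if (n < 2L) return(NULL)
    i <- seq_len(n - 1L)
    data.frame(
      individual_id = ev$individual_id[i],
      sex = ev$sex[i],
      site = ev$site[i],
      l_start_mm = ev$svl_mm[i],
      l_end_mm = ev$svl_mm[i + 1L],
      delta_days = days_between(ev$date[i], ev$date[i + 1L]),
      start_date = ev$date[i],
      end_date = ev$date[i + 1L],
      stringsAsFactors = FALSE
    )
  })
  inc <- do.call(rbind, pieces)
  if (is.null(inc)) {
    inc <- data.frame(individual_id = character(), sex = character(),
                      site = character(), l_start_mm = numeric(),
                      l_end_mm = numeric(), delta_days = integer(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      stringsAsFactors = FALSE)
  }
  rownames(inc) <- NULL
  stop_if(any(inc$delta_days <= 0), "non-positive increment interval")
  shrink <- inc$l_start_mm - inc$l_end_mm
  if (any(shrink > 3 * shrink_warn_sd)) {
    warning(sum(shrink > 3 * shrink_warn_sd),
            " increment(s) show apparent shrinkage beyond 3 residual SDs",
            call. = FALSE)
  }
  inc
}

#' Assemble a capture dataset
#'
#' Combines capture events, individuals and survey occasions into the
#' container used by the model-fitting functions.  The binary detection
#' array is represented sparsely: each capture event is matched to its survey
#' occasion, and [detection_matrix()] materializes the individual-by-occasion
#' matrix for one site.
#'
#' @param events,individuals as returned by [read_captures()].
#' @param surveys as returned by [read_surveys()].
#' @return object of class `capture_dataset`.
#' @export
capture_dataset <- function(events, individuals, surveys) {
  key_e <- paste(events$site, events$date)
  key_s <- paste(surveys$site, surveys$date)
  idx <- match(key_e, key_s)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " capture event(s) fall outside survey ",
            "occasions and are excluded from the detection array",
            call. = FALSE)
  }
  events$occasion <- idx
  events$primary_index <- surveys$primary_index[idx]
  events$secondary_index <- surveys$secondary_index[idx]
  structure(list(events = events, individuals = individuals,
                 surveys = surveys),
            class = "capture_dataset")
}

#' Binary detection matrix for one site
#'
#' @param dataset a [capture_dataset()].
#' @param site site identifier.
#' @return binary matrix, individuals of that site by survey occasions of
#'   that site (columns ordered by primary then secondary index).
#' @export
detection_matrix <- function(dataset, site) {
  occ <- dataset$surveys[dataset$surveys$site == site, , drop = FALSE]
  occ <- occ[order(occ$primary_index, occ$secondary_index), , drop = FALSE]
  ids <- dataset$individuals$id[dataset$individuals$site == site]
  m <- matrix(0L, nrow = length(ids), ncol = nrow(occ),
              dimnames = list(ids, format(occ$date, "%Y-%m-%d")))
  ev <- dataset$events[dataset$events$site == site &
                         !is.na(dataset$events$occasion), , drop = FALSE]
  j <- match(paste(ev$site, ev$date), paste(occ$site, occ$date))
  i <- match(ev$individual_id, ids)
  keep <- !is.na(i) & !is.na(j)
  m[cbind(i[keep], j[keep])] <- 1L
  m
}

#' Restrict a dataset to individuals usable in the CMR model
#'
#' Individuals first captured in the final sampling year of their site carry
#' no information about survival (there is no later occasion on which they
#' could be recaptured) and are removed; they remain usable for growth.
#'
#' @param dataset a [capture_dataset()].
#' @param site_final_year optional named vector mapping site to its final
#'   sampled year; by default the last survey year per site.
#' @return filtered `capture_dataset`.
#' @export
filter_cmr_individuals <- function(dataset, site_final_year = NULL) {
  if (is.null(site_final_year)) {
    site_final_year <- vapply(split(dataset$surveys$year,
                                    dataset$surveys$site), max, numeric(1))
  }
  first_year <- as.integer(format(dataset$individuals$first_capture_date,
                                  "%Y"))
  final <- site_final_year[dataset$individuals$site]
  keep <- first_year < final
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    warning("all individuals were first captured in their site's final ",
            "year; the CMR dataset is empty", call. = FALSE)
  }
  ids <- dataset$individuals$id[keep]
  out <- dataset
  out$individuals <- dataset$individuals[keep, , drop = FALSE]
  out$events <- dataset$events[dataset$events$individual_id %in% ids, ,
                               drop = FALSE]
  rownames(out$individuals) <- rownames(out$events) <- NULL
  out
}

#' Summary table for a capture dataset
#'
#' Reports, per site and overall: number of individuals, capture events, sex
#' breakdown, number of individuals detected in exactly 1, 2, and 3 or more
#' distinct years, number of growth increments, and the mean and SD of the
#' increment interval in days.
#'
#' @param dataset a [capture_dataset()].
#' @return data frame with one row per site plus a final `overall` row.
#' @export
summarize_dataset <- function(dataset) {
  # a summary should report, not warn; shrinkage diagnostics belong to
  # build_growth_increments() when called directly
  inc <- suppressWarnings(build_growth_increments(dataset$events))
  one_site <- function(ids, evs, incs, label) {
    yrs <- tapply(as.integer(format(evs$date, "%Y")), evs$individual_id,
                  function(y) length(unique(y)))
    data.frame(
      site = label,
      individuals = length(ids$id),
      captures = nrow(evs),
      females = sum(ids$sex == "female"),
      males = sum(ids$sex == "male"),
      unknown_sex = sum(ids$sex == "unknown"),
      years_1 = sum(yrs == 1),
      years_2 = sum(yrs == 2),
      years_3plus = sum(yrs >= 3),
      growth_increments = nrow(incs),
      interval_mean_days = if (nrow(incs)) mean(incs$delta_days) else 0,
      interval_sd_days = if (nrow(incs) > 1) sd(incs$delta_days) else 0,
      stringsAsFactors = FALSE
    )
  }
  sites <- sort(unique(dataset$individuals$site))
  rows <- lapply(sites, function(s) {
    one_site(dataset$individuals[dataset$individuals$site == s, ],
             dataset$events[dataset$events$site == s, , drop = FALSE],
             inc[inc$site == s, , drop = FALSE], s)
  })
  rows <- c(rows, list(one_site(dataset$individuals, dataset$events, inc,
                                "overall")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
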