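test_that("capture reading parses, normalizes sex, and keeps missing SVL", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,site,date,sex,svl_mm,mass_g",
               "S001,C,2008-04-12,F,455,61",
               "S001,C,2009-05-02,F,470,",
               "S002,C,2008-04-15,M,,",
               "S003,I,2015-04-20,,312,40"), path)
  cap <- read_captures(path)
  expect_equal(nrow(cap$events), 4)
  expect_equal(cap$events$sex[1], "female")
  expect_equal(cap$events$svl_mm[1], 455)
  expect_true(is.na(cap$events$svl_mm[3]))
  expect_equal(cap$individuals$sex[cap$individuals$id == "S003"], "unknown")
  expect_equal(cap$individuals$first_capture_date[1],
               as.Date("2008-04-12"))
})

test_that("capture reading rejects duplicates and bad dates, naming rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,site,date,sex,svl_mm,mass_g",
               "S001,C,2008-04-12,F,455,61",
               "S001,C,2008-04-12,F,460,62"), path)
  expect_error(read_captures(path), "duplicate.*row 2")
  writeLines(c("individual_id,site,date,sex,svl_mm,mass_g",
               "S001,C,2014-02-29,F,455,61"), path)
  expect_error(read_captures(path), "unparseable date.*row 1")
})

test_that("survey reading assigns indices by year and day rank", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,date,air_temp_c,rel_humidity_pct,precip_24h",
               "C,2014-04-02,15,70,0",
               "C,2014-04-01,14,75,1",
               "C,2014-04-03,16,65,0",
               "C,2015-04-01,13,80,0",
               "I,2014-04-02,18,60,0"), path)
  occ <- read_surveys(path)
  c14 <- occ[occ$site == "C" & occ$year == 2014, ]
  expect_equal(c14$secondary_index, 1:3)
  expect_equal(unique(occ$primary_index[occ$site == "C" &
                                          occ$year == 2015]), 2)
  expect_equal(occ$primary_index[occ$site == "I"], 1)
  writeLines(c("site,date,air_temp_c,rel_humidity_pct,precip_24h",
               "C,2014-04-01,,70,0"), path)
  expect_error(read_surveys(path), "missing survey covariate")
})

test_that("write/read round trips reproduce captures and surveys exactly", {
  cfg <- simulation_config(
    n_years = c(C = 3, I = 2), start_year = c(C = 2012, I = 2013),
    occasions_per_year = 6L, n_individuals = c(C = 60, I = 40))
  sim <- simulate_study(cfg, seed = 9)
  cpath <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_captures(sim$dataset$events, cpath)
  write_surveys(sim$dataset$surveys, spath)
  cap2 <- read_captures(cpath)
  occ2 <- read_surveys(spath)
  ev1 <- sim$dataset$events[c("individual_id", "site", "date", "sex",
                              "svl_mm", "mass_g")]
  rownames(ev1) <- NULL
  expect_equal(cap2$events, ev1)
  keep <- c("site", "date", "air_temp_c", "rel_humidity_pct", "precip_24h",
            "year", "day_of_year", "primary_index", "secondary_index")
  sv1 <- sim$dataset$surveys[keep]
  rownames(sv1) <- rownames(occ2) <- NULL
  expect_equal(occ2[keep], sv1)
})

test_that("increments pair consecutive measured captures only", {
  ev <- make_events(
    c("a", "a", "a", "b", "b", "c"), "C",
    c("2007-05-01", "2008-09-20", "2009-05-01",
      "2010-05-01", "2010-05-03", "2011-05-01"),
    "female", c(455, 502, NA, 300, 310, 400))
  inc <- build_growth_increments(ev)
  # a: one pair (the NA drops the third capture); b: one within-year pair
  expect_equal(nrow(inc), 2)
  expect_equal(inc$delta_days[inc$individual_id == "a"], 508)
  expect_equal(inc$l_start_mm[inc$individual_id == "a"], 455)
  single <- make_events("z", "C", "2010-05-01", "male", 400)
  expect_equal(nrow(build_growth_increments(single)), 0)
  shrunk <- make_events(c("s", "s"), "C", c("2010-05-01", "2011-05-01"),
                        "male", c(500, 380))
  expect_warning(build_growth_increments(shrunk), "shrinkage")
})

test_that("increment counts equal sum of measured captures minus one", {
  cfg <- simulation_config(
    n_years = c(C = 4, I = 3), start_year = c(C = 2011, I = 2012),
    occasions_per_year = 10L, n_individuals = c(C = 150, I = 80))
  sim <- simulate_study(cfg, seed = 14)
  ev <- sim$dataset$events
  inc <- suppressWarnings(build_growth_increments(ev))
  measured <- ev[!is.na(ev$svl_mm), ]
  expected <- sum(pmax(table(measured$individual_id) - 1, 0))
  expect_equal(nrow(inc), as.numeric(expected))
})

test_that("detection matrix is 1 exactly where capture events exist", {
  cfg <- simulation_config(
    n_years = c(C = 3, I = 2), start_year = c(C = 2012, I = 2013),
    occasions_per_year = 8L, n_individuals = c(C = 80, I = 50))
  sim <- simulate_study(cfg, seed = 15)
  ds <- sim$dataset
  for (s in c("C", "I")) {
    dm <- detection_matrix(ds, s)
    ev_s <- ds$events[ds$events$site == s, ]
    expect_equal(sum(dm), nrow(ev_s))
    counts <- table(ev_s$individual_id)
    expect_equal(unname(rowSums(dm)[names(counts)]),
                 as.numeric(counts))
  }
})

test_that("final-year first captures are excluded from the CMR dataset", {
  ev <- make_events(
    c("old", "old", "new"), "C",
    c("2019-05-01", "2020-05-01", "2020-05-02"),
    "female", c(400, 430, 380))
  ind <- make_individuals(ev)
  occ <- make_surveys_for(ev)
  ds <- capture_dataset(ev, ind, occ)
  kept <- filter_cmr_individuals(ds)
  expect_equal(kept$individuals$id, "old")
  expect_false("new" %in% kept$events$individual_id)
  only_new <- capture_dataset(ev[3, ], ind[ind$id == "new", ],
                              make_surveys_for(ev[3, ]))
  expect_warning(empty <- filter_cmr_individuals(only_new), "empty")
  expect_equal(nrow(empty$individuals), 0)
})

test_that("dataset summary reproduces printed-style bookkeeping", {
  s <- summarize_dataset(capture_dataset(
    make_events(character(0), character(0), as.Date(character(0)),
                character(0), numeric(0)),
    data.frame(id = character(0), sex = character(0), site = character(0),
               first_capture_date = as.Date(character(0)),
               first_svl_mm = numeric(0)),
    make_surveys_for(data.frame(site = "C", date = "2010-04-01"))))
  expect_true(all(s[s$site == "overall",
                    c("individuals", "captures", "growth_increments")] == 0))
})
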