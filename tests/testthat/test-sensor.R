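# Geofence classification, imputation and daily aggregation.

test_that("haversine distance is zero at identity and symmetric", {
  expect_identical(haversine_m(35, 33, 35, 33), 0)
  set.seed(101)
  lat1 <- runif(1000, -90, 90); lon1 <- runif(1000, -180, 180)
  lat2 <- runif(1000, -90, 90); lon2 <- runif(1000, -180, 180)
  expect_equal(haversine_m(lat1, lon1, lat2, lon2),
               haversine_m(lat2, lon2, lat1, lon1))
})

test_that("haversine agrees with an independent spherical-law-of-cosines oracle", {
  # ~100 m of latitude at 35 N
  d <- haversine_m(35, 33, 35.0009, 33)
  expect_equal(d, oracle_sloc_m(35, 33, 35.0009, 33), tolerance = 1e-6)
  expect_gt(d, 95); expect_lt(d, 105)
  set.seed(7)
  la <- runif(200, -60, 60); lo <- runif(200, -170, 170)
  lb <- la + runif(200, -0.5, 0.5); lob <- lo + runif(200, -0.5, 0.5)
  expect_equal(haversine_m(la, lo, lb, lob),
               oracle_sloc_m(la, lo, lb, lob), tolerance = 1e-6)
})

test_that("out-of-range coordinates are rejected", {
  expect_error(haversine_m(91, 0, 0, 0), "latitude")
  expect_error(haversine_m(0, 181, 0, 0), "longitude")
})

test_that("geofence classification uses an inclusive 100 m boundary", {
  home <- c(35.17, 33.36)
  near <- c(35.17009, 33.36)   # ~10 m north
  expect_identical(classify_interval(near[1], near[2], home[1], home[2]),
                   "AT_HOME")
  far <- c(35.175, 33.36)      # ~550 m
  expect_identical(classify_interval(far[1], far[2], home[1], home[2]),
                   "OUT_HOME")
  expect_identical(classify_interval(NA, NA, home[1], home[2]), "MISSING")
  # exactly at the boundary: radius set to the exact distance => at home
  d <- haversine_m(far[1], far[2], home[1], home[2])
  expect_identical(classify_interval(far[1], far[2], home[1], home[2],
                                     radius_m = d), "AT_HOME")
  expect_identical(classify_interval(far[1], far[2], home[1], home[2],
                                     radius_m = d - 0.01), "OUT_HOME")
})

test_that("carry-forward imputation follows the most recent valid fix", {
  expect_identical(
    as.character(impute_labels(c("AT_HOME", "MISSING", "MISSING", "OUT_HOME"))),
    c("AT_HOME", "AT_HOME", "AT_HOME", "OUT_HOME"))
  # leading gap backward-fills from the next valid fix
  expect_identical(
    as.character(impute_labels(c("MISSING", "OUT_HOME", "MISSING"))),
    c("OUT_HOME", "OUT_HOME", "OUT_HOME"))
  all_missing <- impute_labels(rep("MISSING", 5))
  expect_true(attr(all_missing, "unresolvable"))
  expect_error(impute_labels(c("AT_HOME", "MISSING"),
                             timestamps = as.POSIXct(c("2020-02-04", "2020-02-03"),
                                                     tz = "UTC")),
               "sorted")
})

test_that("imputation matches the brute-force fill oracle on random days", {
  set.seed(202)
  for (i in 1:200) {
    lab <- sample(c("AT_HOME", "OUT_HOME"), 288, replace = TRUE)
    lab[runif(288) < 0.3] <- "MISSING"
    if (all(lab == "MISSING")) lab[1] <- "AT_HOME"
    expect_identical(as.character(impute_labels(lab)), oracle_fill(lab))
  }
})

test_that("wear-day detection needs at least one heart-rate sample", {
  expect_false(detect_wear_day(rep(NA_real_, 288)))
  expect_true(detect_wear_day(c(rep(NA_real_, 287), 80)))
})

make_day <- function(id, date, labels, home = c(35.17, 33.36), steps = 10,
                     hr = 80) {
  n <- length(labels)
  ts <- as.POSIXct(date, tz = "UTC") + seq(0, by = 300, length.out = n)
  lat <- ifelse(labels == "AT_HOME", home[1],
                ifelse(labels == "OUT_HOME", home[1] + 0.01, NA))
  lon <- ifelse(labels == "MISSING", NA, home[2])
  data.frame(participant_id = id, timestamp = ts, lat = lat, lon = lon,
             steps = steps, heart_rate = hr)
}

roster1 <- data.frame(participant_id = "P1", site = "Cyprus",
                      home_lat = 35.17, home_lon = 33.36)

test_that("daily aggregation divides at-home time by a fixed 24 h", {
  iv <- make_day("P1", "2020-02-03", rep("AT_HOME", 288))
  dm <- process_intervals(iv, roster1)
  expect_equal(dm$fraction_home, 1.0)
  expect_equal(dm$total_steps, 288 * 10)
  iv2 <- make_day("P1", "2020-02-03",
                  rep(c("AT_HOME", "OUT_HOME"), each = 144))
  expect_equal(process_intervals(iv2, roster1)$fraction_home, 0.5)
})

test_that("off-grid timestamps floor onto the same 5-min slot and deduplicate", {
  iv <- make_day("P1", "2020-02-03", rep("AT_HOME", 288))
  extra <- iv[1, ]
  extra$timestamp <- extra$timestamp + 30   # same slot after flooring
  expect_warning(dm <- process_intervals(rbind(iv, extra), roster1),
                 "duplicate")
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$fraction_home, 1.0)
})

test_that("duplicate (participant, timestamp) rows keep the first with a warning", {
  iv <- make_day("P1", "2020-02-03", c("AT_HOME", "OUT_HOME"))
  dup <- iv[2, ]; dup$lat <- iv$lat[1]  # conflicting duplicate
  expect_warning(dm <- process_intervals(rbind(iv, dup), roster1),
                 "duplicate")
  expect_equal(dm$fraction_home, 1 * 5 / 1440)  # first row of the pair won
})

test_that("enlarging the geofence radius never decreases fraction_home", {
  co <- simulate_cohort(small_cfg(seed = 9, n = 3, end = "2020-02-09"))
  f <- sapply(c(50, 100, 200, 500), function(r) {
    dm <- process_intervals(co$intervals, co$participants, radius_m = r)
    dm$fraction_home
  })
  expect_true(all(diff(t(f)) >= 0 | is.na(diff(t(f)))))
})

test_that("exclusions remove DDS days and non-wear days with an audit tally", {
  co <- simulate_cohort(small_cfg(seed = 13, n = 4, end = "2020-02-16",
                                  nonwear_day_prob = 0.2))
  dm <- process_intervals(co$intervals, co$participants)
  dds <- data.frame(site = "Cyprus",
                    date = as.Date(c("2020-02-05", "2020-02-10")))
  out <- apply_exclusions(dm, dds, co$participants)
  tally <- attr(out, "exclusions")
  expect_equal(tally$nonwear_days, sum(!dm$wear_day))
  # every wear day on a DDS date is removed, none remain
  expect_false(any(out$date %in% dds$date))
  n_dds_wear <- sum(dm$wear_day & dm$date %in% dds$date)
  expect_equal(tally$dds_days, n_dds_wear)
  expect_equal(nrow(dm), tally$nonwear_days + tally$dds_days +
                 tally$unresolvable_days + tally$retained)
  # empty DDS list leaves wear days untouched
  out2 <- apply_exclusions(dm, dds[0, ], co$participants)
  expect_equal(nrow(out2), sum(dm$wear_day))
  # idempotence: re-applying exclusions to retained rows is a no-op
  out3 <- apply_exclusions(out, dds, co$participants)
  expect_equal(out3[names(out3)], out[names(out)])
})

test_that("recovered non-wear fraction sits within binomial bounds of the configured rate", {
  cfg <- small_cfg(seed = 31, n = 8, end = "2020-03-15",
                   nonwear_day_prob = 0.1)
  co <- simulate_cohort(cfg)
  dm <- process_intervals(co$intervals, co$participants)
  n <- nrow(dm)
  phat <- mean(!dm$wear_day)
  half <- qnorm(0.975) * sqrt(0.1 * 0.9 / n)
  expect_gt(phat, 0.1 - half)
  expect_lt(phat, 0.1 + half)
})

test_that("a participant record with no valid fix at all is unresolvable", {
  iv <- make_day("P1", "2020-02-03", rep("MISSING", 288))
  dm <- process_intervals(iv, roster1)
  expect_true(dm$unresolvable)
  expect_true(is.na(dm$fraction_home))
})
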