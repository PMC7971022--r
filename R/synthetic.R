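# Synthetic-cohort generator: interval-level wearable traces with known
# ground truth, mirroring the structure the analysis assumes.

#' Configuration of the synthetic cohort generator
#'
#' Builds and validates the full parameter set of the generator. The
#' defaults reproduce the study conditions the analysis was designed for:
#' two school-age asthma cohorts (Cyprus n = 53, Greece/Crete n = 55),
#' observed Feb 3 - Apr 26 in both 2019 (restriction-free) and 2020
#' (tiered lockdown), with per-level shifts in the fraction of time spent
#' at home and in daily steps at the magnitudes of the adjusted effect
#' estimates, weekend effects that reverse sign under lockdown, an age
#' gradient on time at home, a gender and humidity gradient on steps,
#' GPS dropout that is worse indoors than outdoors, occasional non-wear
#' days, and a handful of desert-dust-storm days per site-year.
#'
#' @param sites Named list; each site needs \code{n_participants},
#'   \code{home_lat}, \code{home_lon}, \code{baseline_home_fraction},
#'   \code{level_home_shift} (length-3, levels 1-3),
#'   \code{baseline_steps}, \code{level_steps_shift} (length-3),
#'   \code{temp_mean}, \code{rh_mean}, \code{dds_days} (named vector of
#'   counts per year).
#' @param study_windows Data frame with \code{year}, \code{start},
#'   \code{end}; windows must not overlap.
#' @param age_range Integer range of ages in years.
#' @param male_fraction Probability a participant is male.
#' @param weekend_home_delta_baseline,weekend_home_delta_lockdown Weekend
#'   shift of the at-home fraction at level 0, and the additional shift
#'   once any intervention level is active.
#' @param weekend_steps_delta_baseline,weekend_steps_delta_lockdown Same
#'   structure for steps/day.
#' @param age_effect_home At-home fraction change per year of age
#'   (centred at 8.5 y).
#' @param gender_effect_steps Steps/day added for male participants.
#' @param humidity_effect_steps Steps/day per percentage point of relative
#'   humidity above the site mean.
#' @param participant_sd_home,participant_sd_steps Between-participant
#'   (random intercept) standard deviations.
#' @param noise_sd_home,noise_sd_steps Day-to-day residual standard
#'   deviations.
#' @param gps_dropout_prob_indoor,gps_dropout_prob_outdoor Per-interval
#'   probability of a missing fix; indoor must be >= outdoor (signal loss
#'   is worse inside buildings).
#' @param nonwear_day_prob Probability a participant-day is a non-wear day
#'   (no heart-rate samples at all).
#' @param hr_interval_prob On wear days, probability an interval carries a
#'   heart-rate sample.
#' @param geofence_radius_m Radius used to place at-home fixes safely
#'   inside (and out-of-home fixes safely outside) the geofence.
#' @param seed Integer seed; identical config + seed reproduces identical
#'   output.
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(
    sites = list(
      Cyprus = list(
        n_participants = 53, home_lat = 35.17, home_lon = 33.36,
        baseline_home_fraction = 0.438,
        level_home_shift = c(0.414, 0.487, 0.452),
        baseline_steps = 8996,
        level_steps_shift = c(-2531, -3638, -3644),
        temp_mean = 16, rh_mean = 65,
        dds_days = c("2019" = 4, "2020" = 5)
      ),
      Greece = list(
        n_participants = 55, home_lat = 35.34, home_lon = 25.13,
        baseline_home_fraction = 0.524,
        level_home_shift = c(0.143, 0.231, 0.320),
        baseline_steps = 8527,
        level_steps_shift = c(-1191, -2337, -1961),
        temp_mean = 14, rh_mean = 68,
        dds_days = c("2019" = 2, "2020" = 1)
      )
    ),
    study_windows = data.frame(
      year = c(2019, 2020),
      start = c("2019-02-03", "2020-02-03"),
      end = c("2019-04-26", "2020-04-26")
    ),
    age_range = c(6, 11),
    male_fraction = 0.55,
    weekend_home_delta_baseline = 0.109,
    weekend_home_delta_lockdown = -0.18,
    weekend_steps_delta_baseline = -1002,
    weekend_steps_delta_lockdown = 1400,
    age_effect_home = 0.014,
    gender_effect_steps = 1024,
    humidity_effect_steps = -29,
    participant_sd_home = 0.05,
    participant_sd_steps = 1000,
    noise_sd_home = 0.07,
    noise_sd_steps = 2500,
    gps_dropout_prob_indoor = 0.35,
    gps_dropout_prob_outdoor = 0.15,
    nonwear_day_prob = 0.08,
    hr_interval_prob = 0.9,
    geofence_radius_m = 100,
    seed = 1L) {
  # coerce YAML-shaped inputs (lists of maps) to the native structures
  if (is.list(study_windows) && !is.data.frame(study_windows)) {
    study_windows <- do.call(rbind, lapply(study_windows, as.data.frame))
  }
  sites <- lapply(sites, function(s) {
    s$level_home_shift <- as.numeric(unlist(s$level_home_shift))
    s$level_steps_shift <- as.numeric(unlist(s$level_steps_shift))
    s$dds_days <- unlist(s$dds_days)
    s
  })
  cfg <- list(
    sites = sites, study_windows = study_windows, age_range = age_range,
    male_fraction = male_fraction,
    weekend_home_delta_baseline = weekend_home_delta_baseline,
    weekend_home_delta_lockdown = weekend_home_delta_lockdown,
    weekend_steps_delta_baseline = weekend_steps_delta_baseline,
    weekend_steps_delta_lockdown = weekend_steps_delta_lockdown,
    age_effect_home = age_effect_home,
    gender_effect_steps = gender_effect_steps,
    humidity_effect_steps = humidity_effect_steps,
    participant_sd_home = participant_sd_home,
    participant_sd_steps = participant_sd_steps,
    noise_sd_home = noise_sd_home, noise_sd_steps = noise_sd_steps,
    gps_dropout_prob_indoor = gps_dropout_prob_indoor,
    gps_dropout_prob_outdoor = gps_dropout_prob_outdoor,
    nonwear_day_prob = nonwear_day_prob,
    hr_interval_prob = hr_interval_prob,
    geofence_radius_m = geofence_radius_m,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  probs <- c(cfg$male_fraction, cfg$gps_dropout_prob_indoor,
             cfg$gps_dropout_prob_outdoor, cfg$nonwear_day_prob,
             cfg$hr_interval_prob,
             vapply(cfg$sites, function(s) s$baseline_home_fraction, 0))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$gps_dropout_prob_indoor < cfg$gps_dropout_prob_outdoor) {
    stop("indoor GPS dropout must be >= outdoor dropout", call. = FALSE)
  }
  n <- vapply(cfg$sites, function(s) s$n_participants, 0)
  if (length(n) == 0 || any(n < 1)) {
    stop("each site needs at least one participant", call. = FALSE)
  }
  w <- cfg$study_windows
  if (nrow(w) == 0) stop("study windows must be non-empty", call. = FALSE)
  s <- as.Date(w$start); e <- as.Date(w$end)
  if (any(e < s)) stop("study window ends before it starts", call. = FALSE)
  o <- order(s)
  if (nrow(w) > 1 && any(s[o][-1] <= e[o][-nrow(w)])) {
    stop("study windows must not overlap", call. = FALSE)
  }
  invisible(TRUE)
}

window_dates <- function(study_windows) {
  do.call(c, lapply(seq_len(nrow(study_windows)), function(i) {
    seq(as.Date(study_windows$start[i]), as.Date(study_windows$end[i]),
        by = "day")
  }))
}

# offset a coordinate by (dx, dy) metres on the local tangent plane
offset_coord <- function(lat, lon, dx_m, dy_m) {
  list(lat = lat + dy_m / 111320,
       lon = lon + dx_m / (111320 * cos(lat * pi / 180)))
}

#' Simulate a wearable-sensor cohort with known ground truth
#'
#' Draws a participant roster, per-day true outcomes (at-home occupancy
#' fraction and daily step total) under the configured level, weekend,
#' age, gender and humidity effects, and -- unless
#' \code{intervals = FALSE} -- expands each wear day into 288 five-minute
#' interval records: a two-state (home/away) schedule of contiguous bouts
#' whose home dwell matches the day's true occupancy, GPS fixes placed
#' inside the geofence when home (with margin) and 150-2000 m away
#' otherwise, interval-level GPS dropout (worse indoors), step counts
#' distributed over intervals so the daily sum is exact (near-zero rate
#' while home during 00:00-06:00), and heart-rate samples on wear days
#' only.
#'
#' The emitted \code{truth} table stores the realised occupancy (a
#' multiple of 1/288) so that, with zero dropout and zero non-wear, the
#' processing pipeline recovers it exactly.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param intervals If \code{FALSE}, skip interval expansion and return
#'   only roster, truth, weather and DDS tables -- the fast path for
#'   simulation studies of the inference stage.
#' @return List with \code{participants}, \code{intervals} (or NULL),
#'   \code{weather}, \code{dds_days}, \code{truth} and the \code{config}.
#' @export
simulate_cohort <- function(config, intervals = TRUE) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  validate_synthetic_config(config)
  set.seed(config$seed)
  calendars <- builtin_calendars()
  dates <- window_dates(config$study_windows)

  participants <- make_roster(config)
  weather <- make_weather(config, dates)
  dds_days <- make_dds(config)
  truth <- make_truth(config, participants, weather, calendars, dates)
  iv <- NULL
  if (intervals) iv <- expand_intervals(config, participants, truth)
  list(participants = participants, intervals = iv, weather = weather,
       dds_days = dds_days, truth = truth, config = config)
}

make_roster <- function(config) {
  rows <- lapply(names(config$sites), function(s) {
    sc <- config$sites[[s]]
    n <- sc$n_participants
    id <- sprintf("%s%03d", toupper(substr(s, 1, 2)), seq_len(n))
    home <- offset_coord(sc$home_lat, sc$home_lon,
                         stats::runif(n, -3000, 3000),
                         stats::runif(n, -3000, 3000))
    # eligibility: physician diagnosis plus >= 1 further criterion
    crit <- matrix(stats::rbinom(n * 4, 1, c(0.6, 0.55, 0.35, 0.2)),
                   nrow = n, byrow = TRUE)
    none <- rowSums(crit) == 0
    crit[none, 1] <- 1L   # guarantee eligibility
    data.frame(
      participant_id = id, site = s,
      age_years = sample(seq(config$age_range[1], config$age_range[2]),
                         n, replace = TRUE),
      gender = ifelse(stats::runif(n) < config$male_fraction, "M", "F"),
      home_lat = home$lat, home_lon = home$lon,
      wheezing = crit[, 1] == 1,
      preventive_medication = crit[, 2] == 1,
      unscheduled_visits = crit[, 3] == 1,
      er_visits = crit[, 4] == 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

make_weather <- function(config, dates) {
  rows <- lapply(names(config$sites), function(s) {
    sc <- config$sites[[s]]
    n <- length(dates)
    ar1 <- function(mu, sd, phi = 0.7) {
      e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
      x <- numeric(n)
      x[1] <- mu + stats::rnorm(1, 0, sd)
      for (i in 2:n) x[i] <- mu + phi * (x[i - 1] - mu) + e[i]
      x
    }
    data.frame(site = s, date = dates,
               temp_c = round(ar1(sc$temp_mean, 2.5), 1),
               rh_pct = round(pmin(100, pmax(20, ar1(sc$rh_mean, 8))), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

make_dds <- function(config) {
  rows <- list()
  for (s in names(config$sites)) {
    dd <- config$sites[[s]]$dds_days
    for (yr in names(dd)) {
      k <- dd[[yr]]
      if (k <= 0) next
      w <- config$study_windows[config$study_windows$year == as.numeric(yr), ]
      if (nrow(w) == 0) next
      span <- seq(as.Date(w$start[1]), as.Date(w$end[1]), by = "day")
      rows[[paste(s, yr)]] <- data.frame(
        site = s, date = sort(sample(span, k)), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(site = character(0), date = as.Date(character(0))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

make_truth <- function(config, participants, weather, calendars, dates) {
  grid <- expand.grid(participant_id = participants$participant_id,
                      date = dates, stringsAsFactors = FALSE)
  idx <- match(grid$participant_id, participants$participant_id)
  site <- participants$site[idx]
  sc <- config$sites
  n_p <- nrow(participants)
  b_home <- stats::rnorm(n_p, 0, config$participant_sd_home)
  b_steps <- stats::rnorm(n_p, 0, config$participant_sd_steps)

  level <- integer(nrow(grid))
  for (s in unique(site)) {
    sel <- site == s
    level[sel] <- assign_level(calendars[[s]], grid$date[sel])
  }
  weekend <- format(grid$date, "%u") %in% c("6", "7")
  rh <- weather$rh_pct[match(paste(site, grid$date),
                             paste(weather$site, weather$date))]

  base_home <- vapply(sc, function(x) x$baseline_home_fraction, 0)[site]
  base_steps <- vapply(sc, function(x) x$baseline_steps, 0)[site]
  rh_mean <- vapply(sc, function(x) x$rh_mean, 0)[site]
  shift_home <- shift_steps <- numeric(nrow(grid))
  for (s in unique(site)) {
    for (k in 1:3) {
      sel <- site == s & level == k
      shift_home[sel] <- sc[[s]]$level_home_shift[k]
      shift_steps[sel] <- sc[[s]]$level_steps_shift[k]
    }
  }
  wk_home <- weekend * (config$weekend_home_delta_baseline +
                          (level > 0) * config$weekend_home_delta_lockdown)
  wk_steps <- weekend * (config$weekend_steps_delta_baseline +
                           (level > 0) * config$weekend_steps_delta_lockdown)
  age_c <- participants$age_years[idx] - 8.5
  male <- participants$gender[idx] == "M"

  mu_home <- base_home + shift_home + wk_home +
    config$age_effect_home * age_c + b_home[idx]
  mu_steps <- base_steps + shift_steps + wk_steps +
    config$gender_effect_steps * male +
    config$humidity_effect_steps * (rh - rh_mean) + b_steps[idx]

  f <- pmin(1, pmax(0, mu_home + stats::rnorm(nrow(grid), 0,
                                              config$noise_sd_home)))
  # realised occupancy lives on the 5-min grid
  h <- round(f * 288)
  steps <- pmax(0, round(mu_steps + stats::rnorm(nrow(grid), 0,
                                                 config$noise_sd_steps)))
  wear <- stats::runif(nrow(grid)) >= config$nonwear_day_prob

  out <- data.frame(
    participant_id = grid$participant_id,
    site = site,
    date = grid$date,
    year = as.integer(format(grid$date, "%Y")),
    level = level,
    weekend = weekend,
    wear = wear,
    true_home_fraction = h / 288,
    true_steps = as.integer(steps),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$participant_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# split total t into k positive integer parts (k <= t), uniformly-ish
split_runs <- function(t, k) {
  if (k <= 1) return(t)
  cuts <- sort(sample(seq_len(t - 1), k - 1))
  diff(c(0, cuts, t))
}

# one day's home/away schedule: contiguous bouts, home dwell == h slots
day_schedule <- function(h) {
  n <- 288L
  if (h >= n) return(rep(TRUE, n))
  if (h <= 0) return(rep(FALSE, n))
  a <- n - h
  if (h < 2L) return(c(rep(TRUE, h), rep(FALSE, a)))
  k_away <- sample(seq_len(min(3L, a, h - 1L)), 1)
  away_runs <- split_runs(a, k_away)
  home_runs <- split_runs(h, k_away + 1)
  sched <- logical(0)
  for (i in seq_len(k_away)) {
    sched <- c(sched, rep(TRUE, home_runs[i]), rep(FALSE, away_runs[i]))
  }
  c(sched, rep(TRUE, home_runs[k_away + 1]))
}

expand_intervals <- function(config, participants, truth) {
  slots <- seq(0, by = 300, length.out = 288)
  asleep <- rep(seq_len(288) <= 72, length.out = 288)  # 00:00-06:00
  margin <- 0.8 * config$geofence_radius_m
  p_in <- config$gps_dropout_prob_indoor
  p_out <- config$gps_dropout_prob_outdoor

  idx <- match(truth$participant_id, participants$participant_id)
  n_days <- nrow(truth)
  N <- n_days * 288L
  lat <- lon <- rep(NA_real_, N)
  steps <- hr <- rep(NA_integer_, N)
  tstamp <- numeric(N)
  for (i in seq_len(n_days)) {
    at <- (i - 1L) * 288L + seq_len(288L)
    tstamp[at] <- as.numeric(as.POSIXct(truth$date[i], tz = "UTC")) + slots
    if (!truth$wear[i]) next
    h <- as.integer(round(truth$true_home_fraction[i] * 288))
    at_home <- day_schedule(h)
    has_fix <- stats::runif(288) >= ifelse(at_home, p_in, p_out)
    # at-home fixes: uniform in a disc of radius `margin` around home
    r <- ifelse(at_home, margin * sqrt(stats::runif(288)),
                stats::runif(288, 150, 2000))
    theta <- stats::runif(288, 0, 2 * pi)
    cc <- offset_coord(participants$home_lat[idx[i]],
                       participants$home_lon[idx[i]],
                       r * cos(theta), r * sin(theta))
    lat[at] <- ifelse(has_fix, cc$lat, NA_real_)
    lon[at] <- ifelse(has_fix, cc$lon, NA_real_)
    # interval steps: multinomial split of the true daily total
    wgt <- ifelse(at_home, ifelse(asleep, 0.05, 1), 4)
    steps[at] <- as.integer(stats::rmultinom(1, truth$true_steps[i], wgt))
    hrd <- ifelse(stats::runif(288) < config$hr_interval_prob,
                  pmin(180L, pmax(50L, as.integer(round(
                    stats::rnorm(288, 85, 12))))), NA_integer_)
    if (all(is.na(hrd))) hrd[sample(288, 1)] <- 85L  # wear day => >=1 sample
    hr[at] <- hrd
  }
  out <- data.frame(
    participant_id = rep(truth$participant_id, each = 288L),
    timestamp = as.POSIXct(tstamp, origin = "1970-01-01", tz = "UTC"),
    lat = lat, lon = lon, steps = steps, heart_rate = as.integer(hr),
    stringsAsFactors = FALSE
  )
  out
}

#' Convert generator truth into pipeline-shaped daily metrics
#'
#' Fast path for inference simulation studies: yields the table
#' \code{\link{process_intervals}} would produce under perfect sensing
#' (wear days only, no dropout), directly from the generator's ground
#' truth.
#'
#' @param truth The \code{truth} element of \code{\link{simulate_cohort}}.
#' @return Daily metrics data frame.
#' @export
truth_to_daily <- function(truth) {
  keep <- truth$wear
  data.frame(
    participant_id = truth$participant_id[keep],
    date = truth$date[keep],
    fraction_home = truth$true_home_fraction[keep],
    total_steps = truth$true_steps[keep],
    wear_day = TRUE,
    n_valid_gps = 288L,
    n_imputed = 0L,
    unresolvable = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Write a simulated cohort bundle to CSV files
#'
#' Writes participants.csv, intervals.csv, weather.csv, dds_days.csv and
#' truth.csv into \code{dir}. Timestamps are ISO-8601 local clock time;
#' missing GPS/heart-rate fields are empty. A fixed seed and config give
#' byte-identical files.
#'
#' @param cohort Result of \code{\link{simulate_cohort}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(participants = file.path(dir, "participants.csv"),
             weather = file.path(dir, "weather.csv"),
             dds_days = file.path(dir, "dds_days.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(cohort$participants, paths["participants"],
                   row.names = FALSE)
  utils::write.csv(cohort$weather, paths["weather"], row.names = FALSE)
  utils::write.csv(cohort$dds_days, paths["dds_days"], row.names = FALSE)
  utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  if (!is.null(cohort$intervals)) {
    p <- file.path(dir, "intervals.csv")
    iv <- cohort$intervals
    iv$timestamp <- format(iv$timestamp, "%Y-%m-%dT%H:%M:%S")
    utils::write.csv(iv, p, row.names = FALSE, na = "")
    paths <- c(paths, intervals = p)
  }
  invisible(paths)
}
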