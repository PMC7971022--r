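# Independent oracles and fixture builders used across the suite.

# spherical law of cosines on the same 6,371,000 m sphere -- an
# independently coded distance check for haversine_m()
oracle_sloc_m <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371000 * acos(pmin(1, pmax(-1, d)))
}

# brute-force forward/backward fill of MISSING labels
oracle_fill <- function(labels) {
  out <- labels
  last <- NA_character_
  for (i in seq_along(out)) {
    if (out[i] == "MISSING") {
      if (!is.na(last)) out[i] <- last
    } else {
      last <- out[i]
    }
  }
  nxt <- NA_character_
  for (i in rev(seq_along(out))) {
    if (out[i] == "MISSING") {
      if (!is.na(nxt)) out[i] <- nxt
    } else {
      nxt <- out[i]
    }
  }
  out
}

# one-way ANOVA F statistic from explicit sums of squares
oracle_anova_F <- function(y, g) {
  g <- as.factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# ordinary least squares through the normal equations
oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# a reduced synthetic configuration for fast tests
small_cfg <- function(seed = 1, n = 4, sites = "Cyprus",
                      start = "2020-02-03", end = "2020-02-23", ...) {
  cfg <- synthetic_config(seed = seed)
  for (s in setdiff(names(cfg$sites), sites)) cfg$sites[[s]] <- NULL
  for (s in sites) cfg$sites[[s]]$n_participants <- n
  yrs <- as.integer(substr(start, 1, 4))
  cfg$study_windows <- data.frame(year = yrs, start = start, end = end)
  for (s in sites) {
    keep <- names(cfg$sites[[s]]$dds_days) %in% as.character(yrs)
    cfg$sites[[s]]$dds_days <- cfg$sites[[s]]$dds_days[keep]
  }
  dots <- list(...)
  for (k in names(dots)) cfg[[k]] <- dots[[k]]
  cfg
}

# Cyprus-only configuration with all systematic effects zeroed: only
# random intercepts and day-to-day noise remain
null_cfg <- function(seed) {
  cfg <- synthetic_config(seed = seed)
  cfg$sites$Greece <- NULL
  cfg$sites$Cyprus$level_home_shift <- c(0, 0, 0)
  cfg$sites$Cyprus$level_steps_shift <- c(0, 0, 0)
  cfg$weekend_home_delta_baseline <- 0
  cfg$weekend_home_delta_lockdown <- 0
  cfg$weekend_steps_delta_baseline <- 0
  cfg$weekend_steps_delta_lockdown <- 0
  cfg$age_effect_home <- 0
  cfg$gender_effect_steps <- 0
  cfg$humidity_effect_steps <- 0
  cfg
}

# analysis table straight from generator truth (perfect-sensing path)
truth_table <- function(cohort, ...) {
  annotate_days(truth_to_daily(cohort$truth), cohort$participants,
                cohort$weather, ...)
}
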