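# Covariate annotation: intervention level, weekend, year, weather and
# harmonic seasonal terms for each retained participant-day.

#' Attach analysis covariates to daily metrics
#'
#' Joins the participant roster and site weather onto the daily metrics and
#' derives the model covariates: intervention \code{level} (categorical
#' 0-3, from the site's calendar; any date outside the calendar entries,
#' e.g. the 2019 window, is level 0), \code{weekend} (Saturday/Sunday of
#' the local calendar), \code{year} (factor, 2019 reference),
#' \code{sin_t}/\code{cos_t} (one harmonic pair with period
#' \code{period_days} absorbing monthly variability) and
#' weekend-by-level indicator columns for levels 1-3.
#'
#' Weather is joined on (site, date); gaps up to \code{max_gap_days} are
#' linearly interpolated, longer gaps drop the affected days with a
#' warning.
#'
#' @param daily Daily metrics (after \code{\link{apply_exclusions}}).
#' @param participants Roster with \code{participant_id}, \code{site},
#'   \code{age_years}, \code{gender} and any eligibility columns.
#' @param weather Data frame with \code{site}, \code{date}, \code{temp_c},
#'   \code{rh_pct}.
#' @param calendars Named list of \code{intervention_calendar}s keyed by
#'   site (default \code{\link{builtin_calendars}()}).
#' @param period_days Harmonic period in days (default 30.44, the mean
#'   calendar month).
#' @param max_gap_days Longest weather gap to interpolate across.
#' @return The annotated analysis table; attribute \code{"n_weather_dropped"}
#'   counts days dropped for unfillable weather gaps.
#' @export
annotate_days <- function(daily, participants, weather,
                          calendars = builtin_calendars(),
                          period_days = 30.44, max_gap_days = 2) {
  stopifnot(period_days > 0)
  idx <- match(daily$participant_id, participants$participant_id)
  if (anyNA(idx)) {
    stop("participants missing from roster: ",
         paste(unique(daily$participant_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  out <- daily
  out$site <- participants$site[idx]
  out$age_years <- participants$age_years[idx]
  out$gender <- factor(participants$gender[idx], levels = c("F", "M"))
  out$date <- as.Date(out$date)

  out$level <- NA_integer_
  for (s in unique(out$site)) {
    cal <- calendars[[s]]
    if (is.null(cal)) stop("no calendar for site ", s, call. = FALSE)
    sel <- out$site == s
    out$level[sel] <- assign_level(cal, out$date[sel])
  }
  out$level <- factor(out$level, levels = 0:3)
  out$weekend <- format(out$date, "%u") %in% c("6", "7")
  out$year <- factor(format(out$date, "%Y"))

  # weather join with bounded linear interpolation over daily gaps
  weather$date <- as.Date(weather$date)
  out$temp_c <- NA_real_
  out$rh_pct <- NA_real_
  for (s in unique(out$site)) {
    w <- weather[weather$site == s, , drop = FALSE]
    sel <- which(out$site == s)
    if (nrow(w) == 0) next
    grid <- seq(min(w$date, min(out$date[sel])),
                max(w$date, max(out$date[sel])), by = "day")
    tt <- w$temp_c[match(grid, w$date)]
    hh <- w$rh_pct[match(grid, w$date)]
    tt <- zoo::na.approx(tt, x = as.numeric(grid), maxgap = max_gap_days,
                         na.rm = FALSE)
    hh <- zoo::na.approx(hh, x = as.numeric(grid), maxgap = max_gap_days,
                         na.rm = FALSE)
    m <- match(out$date[sel], grid)
    out$temp_c[sel] <- tt[m]
    out$rh_pct[sel] <- hh[m]
  }
  gap <- is.na(out$temp_c) | is.na(out$rh_pct)
  if (any(gap)) {
    warning(sprintf("dropping %d day(s) with weather gaps beyond %d day(s)",
                    sum(gap), max_gap_days), call. = FALSE)
    out <- out[!gap, , drop = FALSE]
  }

  doy <- as.POSIXlt(out$date)$yday + 1
  out$sin_t <- sin(2 * pi * doy / period_days)
  out$cos_t <- cos(2 * pi * doy / period_days)
  for (k in 1:3) {
    out[[paste0("weekend_level", k)]] <-
      as.integer(out$weekend & out$level == k)
  }
  rownames(out) <- NULL
  attr(out, "n_weather_dropped") <- sum(gap)
  attr(out, "period_days") <- period_days
  out
}

#' Weekly mean series of both outcomes
#'
#' Study weeks are anchored at February 3 of each study year: Feb 3-9 is
#' week 1, Feb 10-16 week 2, and so on, giving the 12-week series plotted
#' against the intervention timeline.
#'
#' @param annotated Analysis table from \code{\link{annotate_days}} (any
#'   table with \code{site}, \code{date}, \code{fraction_home},
#'   \code{total_steps}).
#' @return Data frame with \code{site}, \code{year}, \code{week},
#'   \code{fraction_home}, \code{total_steps} (weekly means) and \code{n}
#'   participant-days.
#' @export
weekly_series <- function(annotated) {
  d <- as.Date(annotated$date)
  yr <- format(d, "%Y")
  anchor <- as.Date(paste0(yr, "-02-03"))
  week <- as.integer(as.numeric(d - anchor) %/% 7L + 1L)
  df <- data.frame(site = as.character(annotated$site), year = yr,
                   week = week,
                   fraction_home = annotated$fraction_home,
                   total_steps = annotated$total_steps)
  out <- stats::aggregate(cbind(fraction_home, total_steps) ~
                            site + year + week,
                          data = df, FUN = mean, na.action = stats::na.omit)
  nn <- stats::aggregate(list(n = df$week),
                         by = list(site = df$site, year = df$year,
                                   week = df$week),
                         FUN = length)
  out$n <- nn$n[match(paste(out$site, out$year, out$week),
                      paste(nn$site, nn$year, nn$week))]
  out <- out[order(out$site, out$year, out$week), , drop = FALSE]
  rownames(out) <- NULL
  out
}
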