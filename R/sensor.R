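# Sensor processing: geofence classification, carry-forward imputation,
# wear-day detection and 24-h aggregation of 5-min interval records.

INTERVALS_PER_DAY <- 288L
INTERVAL_MIN <- 5L

#' Great-circle distance in metres
#'
#' Haversine distance between WGS84 coordinates on a sphere of radius
#' 6,371,000 m. Vectorised over all four arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Numeric vector of non-negative distances in metres.
#' @examples
#' haversine_m(35, 33, 35, 33)        # 0
#' haversine_m(35, 33, 35.0009, 33)   # ~100 m
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000)
}

check_coords <- function(lat, lon) {
  ok_lat <- is.na(lat) | (lat >= -90 & lat <= 90)
  ok_lon <- is.na(lon) | (lon >= -180 & lon <= 180)
  if (!all(ok_lat)) stop("latitude out of range [-90, 90]", call. = FALSE)
  if (!all(ok_lon)) stop("longitude out of range [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Classify 5-min intervals against the home geofence
#'
#' An interval with a valid GPS fix is \code{"AT_HOME"} when its distance to
#' the participant's residence is at most \code{radius_m} (boundary
#' inclusive) and \code{"OUT_HOME"} otherwise; intervals without a fix are
#' \code{"MISSING"}.
#'
#' @param lat,lon Fix coordinates (NA when the fix is missing).
#' @param home_lat,home_lon Residence coordinates.
#' @param radius_m Geofence radius in metres (default 100, the maximum
#'   barrier accounting for consumer GPS accuracy).
#' @return Character vector in \code{c("AT_HOME", "OUT_HOME", "MISSING")}.
#' @export
classify_interval <- function(lat, lon, home_lat, home_lon, radius_m = 100) {
  if (any(radius_m <= 0)) stop("radius_m must be positive", call. = FALSE)
  out <- rep("MISSING", length(lat))
  has_fix <- !is.na(lat) & !is.na(lon)
  if (any(has_fix)) {
    d <- haversine_m(lat[has_fix], lon[has_fix],
                     rep_len(home_lat, length(lat))[has_fix],
                     rep_len(home_lon, length(lat))[has_fix])
    out[has_fix] <- ifelse(d <= rep_len(radius_m, length(lat))[has_fix],
                           "AT_HOME", "OUT_HOME")
  }
  out
}

#' Impute missing interval labels from the nearest valid fix
#'
#' Each \code{"MISSING"} label takes the label of the most recent preceding
#' valid interval (carry-forward, crossing midnight within a participant's
#' contiguous record). A leading run of missing labels with no prior valid
#' fix takes the label of the next valid fix (backward fill). If the whole
#' sequence is missing it is returned unchanged and flagged unresolvable.
#'
#' @param labels Character vector of \code{"AT_HOME"/"OUT_HOME"/"MISSING"},
#'   time-ordered for one participant.
#' @param timestamps Optional POSIXct vector used to verify ordering;
#'   unsorted input is an error.
#' @return Character vector with attributes \code{n_imputed},
#'   \code{longest_run} (longest imputed run) and \code{unresolvable}.
#' @export
impute_labels <- function(labels, timestamps = NULL) {
  if (!is.null(timestamps) && is.unsorted(timestamps)) {
    stop("intervals must be sorted by timestamp", call. = FALSE)
  }
  miss <- labels == "MISSING"
  out <- labels
  if (all(miss)) {
    attr(out, "n_imputed") <- 0L
    attr(out, "longest_run") <- 0L
    attr(out, "unresolvable") <- TRUE
    return(out)
  }
  x <- ifelse(miss, NA_character_, labels)
  x <- zoo::na.locf(x, na.rm = FALSE)            # carry-forward
  x <- zoo::na.locf(x, fromLast = TRUE)          # leading gap: backward fill
  runs <- rle(miss)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  attr(x, "n_imputed") <- sum(miss)
  attr(x, "longest_run") <- as.integer(longest)
  attr(x, "unresolvable") <- FALSE
  x
}

#' Wear-day detection from heart-rate presence
#'
#' A calendar day counts as worn when at least one of its intervals carries
#' a heart-rate measurement; days without any are excluded downstream.
#'
#' @param heart_rate Numeric vector of the day's heart-rate values
#'   (NA = absent).
#' @return Logical flag.
#' @export
detect_wear_day <- function(heart_rate) {
  any(!is.na(heart_rate))
}

#' Process 5-min interval records into daily metrics
#'
#' Validates and normalises raw interval records, classifies each fix
#' against the participant's 100 m home geofence, imputes missing-GPS
#' intervals from the most recent valid fix, detects wear days from
#' heart-rate presence and aggregates to one row per participant-day:
#' \code{fraction_home} = (AT_HOME intervals x 5 min) / 1440 min and
#' \code{total_steps} = sum of non-missing interval steps. The denominator
#' is a fixed 24 h regardless of partially missing step or heart-rate data.
#'
#' Timestamps are floored to the 5-minute grid; duplicate
#' (participant, timestamp) rows keep the first occurrence with a warning.
#' Days of a participant whose whole record has no valid fix are flagged
#' unresolvable: their \code{fraction_home} is NA and \code{wear_day}
#' handling still applies.
#'
#' @param intervals Data frame with columns \code{participant_id},
#'   \code{timestamp} (POSIXct or "YYYY-MM-DD HH:MM:SS" character),
#'   \code{lat}, \code{lon}, \code{steps}, \code{heart_rate}.
#' @param participants Roster with \code{participant_id}, \code{home_lat},
#'   \code{home_lon} (and typically \code{site}).
#' @param radius_m Geofence radius in metres.
#' @return Data frame with one row per participant-day:
#'   \code{participant_id}, \code{date}, \code{fraction_home},
#'   \code{total_steps}, \code{wear_day}, \code{n_valid_gps},
#'   \code{n_imputed}, \code{unresolvable}. A \code{"processing_log"}
#'   attribute records duplicate counts and the longest imputed run.
#' @export
process_intervals <- function(intervals, participants, radius_m = 100) {
  need <- c("participant_id", "timestamp", "lat", "lon", "steps",
            "heart_rate")
  if (!all(need %in% names(intervals))) {
    stop("intervals is missing columns: ",
         paste(setdiff(need, names(intervals)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("participant_id", "home_lat", "home_lon") %in%
           names(participants))) {
    stop("participants must have participant_id, home_lat, home_lon",
         call. = FALSE)
  }
  ts <- intervals$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(sub("T", " ", as.character(ts), fixed = TRUE),
                     tz = "UTC")
    if (anyNA(ts)) stop("unparseable timestamps in intervals", call. = FALSE)
  }
  # local clock time, floored to the 0-based 5-min grid
  ts <- as.POSIXct(floor(as.numeric(ts) / 300) * 300,
                   origin = "1970-01-01", tz = "UTC")
  missing_part <- setdiff(unique(intervals$participant_id),
                          participants$participant_id)
  if (length(missing_part)) {
    stop("participants missing from roster: ",
         paste(missing_part, collapse = ", "), call. = FALSE)
  }
  ord <- order(intervals$participant_id, ts)
  intervals <- intervals[ord, , drop = FALSE]
  ts <- ts[ord]
  dup <- duplicated(data.frame(intervals$participant_id, as.numeric(ts)))
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warning(sprintf("dropping %d duplicate (participant, timestamp) rows; keeping first",
                    n_dup), call. = FALSE)
    intervals <- intervals[!dup, , drop = FALSE]
    ts <- ts[!dup]
  }

  idx <- match(intervals$participant_id, participants$participant_id)
  label <- classify_interval(intervals$lat, intervals$lon,
                             participants$home_lat[idx],
                             participants$home_lon[idx],
                             radius_m = radius_m)

  pid <- as.character(intervals$participant_id)
  date <- as.Date(ts, tz = "UTC")
  imputed <- rep(FALSE, length(label))
  unresolvable_pid <- character(0)
  longest_run <- 0L
  for (p in unique(pid)) {
    sel <- which(pid == p)
    lab <- impute_labels(label[sel])
    if (isTRUE(attr(lab, "unresolvable"))) {
      unresolvable_pid <- c(unresolvable_pid, p)
    } else {
      imputed[sel] <- label[sel] == "MISSING"
      longest_run <- max(longest_run, attr(lab, "longest_run"))
      label[sel] <- as.character(lab)
    }
  }

  key <- paste(pid, date, sep = "\r")
  n_per_day <- table(key)
  if (any(n_per_day > INTERVALS_PER_DAY)) {
    stop("more than 288 intervals in a participant-day", call. = FALSE)
  }
  ukey <- sort(unique(key))
  f <- factor(key, levels = ukey)
  at_home <- tapply(label == "AT_HOME", f, sum)
  steps <- tapply(intervals$steps, f, function(x) sum(x, na.rm = TRUE))
  wear <- tapply(!is.na(intervals$heart_rate), f, any)
  n_valid <- tapply(!is.na(intervals$lat) & !is.na(intervals$lon), f, sum)
  n_imp <- tapply(imputed, f, sum)

  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  out <- data.frame(
    participant_id = parts[, 1],
    date = as.Date(parts[, 2]),
    fraction_home = as.numeric(at_home) * INTERVAL_MIN / 1440,
    total_steps = as.numeric(steps),
    wear_day = as.logical(wear),
    n_valid_gps = as.integer(n_valid),
    n_imputed = as.integer(n_imp),
    stringsAsFactors = FALSE
  )
  out$unresolvable <- out$participant_id %in% unresolvable_pid
  out$fraction_home[out$unresolvable] <- NA_real_
  rownames(out) <- NULL
  attr(out, "processing_log") <- list(
    n_duplicates_dropped = n_dup,
    longest_imputed_run = longest_run,
    n_unresolvable_participants = length(unresolvable_pid),
    radius_m = radius_m
  )
  out
}

#' Apply wear-day and dust-storm-day exclusions
#'
#' Removes participant-days that are non-wear days (no heart-rate sample),
#' unresolvable (no valid GPS fix in the whole record) or fall on a desert
#' dust storm (DDS) day for the participant's site, on which behavioural
#' advice alters mobility.
#'
#' @param daily Output of \code{\link{process_intervals}}.
#' @param dds_days Data frame with columns \code{site}, \code{date}; may
#'   have zero rows.
#' @param participants Roster mapping \code{participant_id} to \code{site}.
#' @return Filtered daily metrics with an \code{"exclusions"} attribute
#'   tallying removals by reason.
#' @export
apply_exclusions <- function(daily, dds_days, participants) {
  site <- participants$site[match(daily$participant_id,
                                  participants$participant_id)]
  dds_key <- character(0)
  if (!is.null(dds_days) && nrow(dds_days) > 0) {
    dds_key <- paste(dds_days$site, as.Date(dds_days$date))
  }
  dds_excluded <- paste(site, daily$date) %in% dds_key
  nonwear <- !daily$wear_day
  unres <- daily$unresolvable
  keep <- !nonwear & !dds_excluded & !unres
  out <- daily[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- list(
    nonwear_days = sum(nonwear),
    dds_days = sum(dds_excluded & !nonwear),
    unresolvable_days = sum(unres & !nonwear & !dds_excluded),
    retained = nrow(out)
  )
  out
}
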