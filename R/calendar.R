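# Tiered intervention calendars and level assignment.

#' Construct an intervention calendar
#'
#' A calendar is an ordered set of date ranges, each carrying an
#' intervention level 0-3. Entries must not overlap, must leave no gap,
#' and levels must be non-decreasing in date order (restrictions only
#' escalate within the observed window).
#'
#' @param site Site label, e.g. \code{"Cyprus"}.
#' @param entries Data frame with columns \code{start}, \code{end} (Date
#'   or "YYYY-MM-DD"), \code{level} (integer 0-3) and optionally
#'   \code{description}.
#' @return An object of class \code{intervention_calendar}.
#' @export
intervention_calendar <- function(site, entries) {
  entries$start <- as.Date(entries$start)
  entries$end <- as.Date(entries$end)
  if (!"description" %in% names(entries)) entries$description <- ""
  entries <- entries[order(entries$start), , drop = FALSE]
  if (any(entries$end < entries$start)) {
    stop("calendar entry ends before it starts", call. = FALSE)
  }
  if (!all(entries$level %in% 0:3)) {
    stop("levels must be in 0..3", call. = FALSE)
  }
  if (nrow(entries) > 1) {
    gaps <- as.numeric(entries$start[-1] - entries$end[-nrow(entries)])
    if (any(gaps != 1)) {
      stop("calendar entries must tile the window without overlap or gap",
           call. = FALSE)
    }
    if (any(diff(entries$level) < 0)) {
      stop("levels must be non-decreasing over time", call. = FALSE)
    }
  }
  structure(list(site = site, entries = entries),
            class = "intervention_calendar")
}

#' @export
print.intervention_calendar <- function(x, ...) {
  cat("Intervention calendar:", x$site, "\n")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Built-in 2020 intervention calendars for Cyprus and Greece
#'
#' The tiered COVID-19 restriction calendars for the Feb 3 - Apr 26, 2020
#' study window. Cyprus: baseline to Mar 12, level 1 Mar 13-24, level 2
#' Mar 25-31, level 3 Apr 1-26. Greece: baseline to Mar 10, level 1
#' Mar 11-15, level 2 Mar 16-22, level 3 Mar 23-Apr 26. Dates outside the
#' entries (in particular the whole 2019 comparison window) assign to
#' level 0.
#'
#' @return Named list of \code{intervention_calendar} objects.
#' @export
builtin_calendars <- function() {
  cy <- data.frame(
    start = c("2020-02-03", "2020-03-13", "2020-03-25", "2020-04-01"),
    end   = c("2020-03-12", "2020-03-24", "2020-03-31", "2020-04-26"),
    level = 0:3,
    description = c(
      "no public health interventions",
      "social distancing; events > 75 banned; bars, restaurants, schools closed",
      "retail and worship closed; movement restricted (3 permissions/day)",
      "stringent lockdown (1 movement permission/day)"
    )
  )
  gr <- data.frame(
    start = c("2020-02-03", "2020-03-11", "2020-03-16", "2020-03-23"),
    end   = c("2020-03-10", "2020-03-15", "2020-03-22", "2020-04-26"),
    level = 0:3,
    description = c(
      "no public health interventions",
      "social distancing; all public events banned; bars, restaurants, schools closed",
      "retail and worship closed; gatherings > 10 banned",
      "movement restricted except subsistence and health needs"
    )
  )
  list(Cyprus = intervention_calendar("Cyprus", cy),
       Greece = intervention_calendar("Greece", gr))
}

#' Assign intervention levels to dates
#'
#' @param calendar An \code{intervention_calendar}.
#' @param dates Date vector (or coercible).
#' @return Integer vector of levels; dates outside all entries (e.g. the
#'   2019 pre-pandemic window) map to level 0.
#' @export
assign_level <- function(calendar, dates) {
  stopifnot(inherits(calendar, "intervention_calendar"))
  dates <- as.Date(dates)
  lev <- rep(0L, length(dates))
  for (i in seq_len(nrow(calendar$entries))) {
    e <- calendar$entries[i, ]
    hit <- dates >= e$start & dates <= e$end
    lev[hit] <- as.integer(e$level)
  }
  lev
}

#' Read intervention calendars from a YAML file
#'
#' Expected structure: a map of site name to a list of entries with
#' \code{start}, \code{end}, \code{level} (and optional
#' \code{description}) keys.
#'
#' @param path YAML file path.
#' @return Named list of \code{intervention_calendar} objects.
#' @export
read_calendars <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(site) {
    entries <- do.call(rbind, lapply(raw[[site]], function(e) {
      data.frame(start = e$start, end = e$end, level = e$level,
                 description = if (is.null(e$description)) "" else e$description)
    }))
    intervention_calendar(site, entries)
  })
  names(out) <- names(raw)
  out
}
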