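# One-command orchestration: simulate -> process -> annotate -> infer,
# with YAML configuration, a run manifest and per-stage error reporting.

#' Default pipeline configuration
#'
#' All analysis defaults in one list: 100 m geofence, 30.44-day harmonic
#' period, 2-day weather interpolation limit, Bonferroni contrast
#' adjustment, built-in intervention calendars, and the default synthetic
#' cohort (used when no input paths are given). Every field can be
#' overridden via a YAML file (\code{\link{load_pipeline_config}}) or by
#' editing the list.
#'
#' @param seed Integer seed.
#' @return A nested list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    simulate = TRUE,
    inputs = list(intervals = NULL, participants = NULL, weather = NULL,
                  dds_days = NULL),
    synthetic = list(seed = as.integer(seed)),
    radius_m = 100,
    period_days = 30.44,
    max_weather_gap_days = 2,
    adjust = "bonferroni",
    calendars_yaml = NULL,
    seed = as.integer(seed)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over
#' \code{\link{default_pipeline_config}}; unspecified fields keep their
#' defaults.
#'
#' @param path YAML file.
#' @param seed Fallback seed if the file sets none.
#' @return A configuration list.
#' @export
load_pipeline_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = seed)
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_lists(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge_lists(cfg, user)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s stage] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) interval-level data, processes it into daily
#' metrics, applies wear-day and dust-storm exclusions, annotates analysis
#' covariates, and computes the observed per-level summaries, the adjusted
#' mixed models with level contrasts, and the weekly series, writing every
#' table plus a run manifest into \code{out_dir}. Any stage failure aborts
#' with an error naming the stage.
#'
#' @param config A configuration list
#'   (\code{\link{default_pipeline_config}} or
#'   \code{\link{load_pipeline_config}}); \code{NULL} for the defaults.
#' @param out_dir Output directory.
#' @param seed Optional override of the configured seed.
#' @param write_intervals Also write the (large) simulated intervals.csv.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL,
                         write_intervals = FALSE) {
  if (is.null(config)) config <- default_pipeline_config()
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$synthetic$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("wearhome")),
                   config = config, stages = list())
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    written <<- c(written, name)
    p
  }

  # --- synthetic_cohort / input stage ----------------------------------
  dat <- stage("synthetic_cohort", {
    if (isTRUE(config$simulate)) {
      sc <- config$synthetic
      sc$seed <- config$seed
      cohort <- simulate_cohort(do.call(synthetic_config, sc))
      if (write_intervals) write_cohort(cohort, out_dir)
      emit(cohort$participants, "participants.csv")
      emit(cohort$weather, "weather.csv")
      emit(cohort$dds_days, "dds_days.csv")
      emit(cohort$truth, "truth.csv")
      cohort
    } else {
      ip <- config$inputs
      for (f in c("intervals", "participants")) {
        if (is.null(ip[[f]]) || !file.exists(ip[[f]])) {
          stop("missing input file for '", f, "'")
        }
      }
      list(
        intervals = utils::read.csv(ip$intervals),
        participants = utils::read.csv(ip$participants),
        weather = NULL,  # read lazily by the study_design stage
        dds_days = if (!is.null(ip$dds_days) && file.exists(ip$dds_days)) {
          utils::read.csv(ip$dds_days)
        } else {
          data.frame(site = character(0), date = character(0))
        }
      )
    }
  })
  manifest$stages$synthetic_cohort <- list(
    n_participants = nrow(dat$participants),
    n_intervals = nrow(dat$intervals)
  )

  # --- sensor_processing stage -----------------------------------------
  retained <- stage("sensor_processing", {
    daily <- process_intervals(dat$intervals, dat$participants,
                               radius_m = config$radius_m)
    out <- apply_exclusions(daily, dat$dds_days, dat$participants)
    emit(out, "daily_metrics.csv")
    out
  })
  manifest$stages$sensor_processing <- c(
    attr(retained, "exclusions"),
    attr(retained, "processing_log")["n_duplicates_dropped"]
  )

  # --- study_design stage ----------------------------------------------
  tab <- stage("study_design", {
    cals <- if (!is.null(config$calendars_yaml)) {
      read_calendars(config$calendars_yaml)
    } else {
      builtin_calendars()
    }
    if (is.null(dat$weather)) {
      wp <- config$inputs$weather
      if (is.null(wp) || !file.exists(wp)) {
        stop("missing input file for 'weather'")
      }
      dat$weather <- utils::read.csv(wp)
    }
    out <- annotate_days(retained, dat$participants, dat$weather,
                         calendars = cals,
                         period_days = config$period_days,
                         max_gap_days = config$max_weather_gap_days)
    emit(out, "analysis_table.csv")
    out
  })
  manifest$stages$study_design <- list(
    n_rows = nrow(tab),
    n_weather_dropped = attr(tab, "n_weather_dropped"),
    period_days = config$period_days
  )

  # --- inference stage --------------------------------------------------
  results <- stage("inference", {
    demo <- describe_cohort(dat$participants)
    emit(demo$summary, "demographics.csv")
    sites <- unique(tab$site)
    obs <- do.call(rbind, lapply(sites, function(s) {
      rbind(level_means(tab, "fraction_home", site = s),
            level_means(tab, "total_steps", site = s))
    }))
    emit(obs, "table_observed.csv")
    model_rows <- list(); contrast_rows <- list()
    for (s in sites) {
      for (oc in c("fraction_home", "total_steps")) {
        fit <- fit_mobility_model(tab, oc, site = s)
        ct <- fit$coefficients
        ct$site <- s; ct$outcome <- oc
        ct$n_obs <- fit$n_obs; ct$n_participants <- fit$n_participants
        model_rows[[paste(s, oc)]] <- ct
        lc <- level_contrasts(fit, adjust = config$adjust)
        lc$site <- s; lc$outcome <- oc
        contrast_rows[[paste(s, oc)]] <- lc
      }
    }
    emit(do.call(rbind, model_rows), "table_model.csv")
    emit(do.call(rbind, contrast_rows), "contrasts.csv")
    emit(weekly_series(tab), "weekly_series.csv")
    invisible(NULL)
  })

  manifest$files <- written
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(manifest)
}
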