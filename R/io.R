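# File formats and configuration: trial CSVs + JSON manifest, study config.

#' Default study configuration
#'
#' All tunable constants of the virtual study in one structure: oscillator
#' defaults, trial counts, the feedback bandwidth schedule, scoring
#' bandwidths, and staircase defaults.
#'
#' @param ... Named overrides of the defaults.
#' @return An object of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    frequency = 1, sample_rate = 60, duration = 20, amplitude = 300,
    assessment_trials = 5, training_trials = 30,
    bandwidth_schedule = c(30, 25, 20, 15, 10),
    scoring_bandwidth = 20, alt_scoring_bandwidth = 10,
    phases = seq(0, 180, by = 30), trained_phase = 90,
    staircase = list(initial_difference = 30, step_up = 10,
                     down_ratio = 0.5488, n_reversal_stop = 8),
    max_training_sessions = 10, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- unlist(cfg[c("frequency", "sample_rate", "duration", "amplitude",
                      "assessment_trials", "training_trials")])
  if (any(num <= 0)) stop("config values must be positive")
  if (any(diff(cfg$bandwidth_schedule) >= 0)) {
    stop("bandwidth schedule must be strictly decreasing")
  }
  structure(cfg, class = "study_config")
}

#' Read or write a study configuration as YAML
#'
#' @param config A [study_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `study_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

#' Write trials to CSV files plus a JSON manifest
#'
#' Each trial becomes a CSV with columns `time_s`, `left_pos`, `right_pos`;
#' `manifest.json` records the metadata (file, session, phase, trial index,
#' and any extra fields supplied).
#'
#' @param trials A list of [trial_time_series()] objects.
#' @param dir Output directory (created if needed).
#' @param meta Optional data frame of extra manifest columns (one row per
#'   trial), e.g. participant id and group.
#' @return The manifest path, invisibly.
#' @export
write_trials <- function(trials, dir, meta = NULL) {
  stopifnot(is.list(trials), length(trials) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    stopifnot(inherits(tr, "trial_time_series"))
    file <- sprintf("trial_%04d.csv", i)
    utils::write.csv(
      data.frame(time_s = tr$time, left_pos = tr$left_position,
                 right_pos = tr$right_position),
      file.path(dir, file), row.names = FALSE)
    rec <- list(file = file, target_phase = tr$target_phase,
                session_index = tr$session_index,
                trial_index = tr$trial_index,
                sample_rate = tr$sample_rate)
    if (!is.null(meta)) rec <- c(rec, as.list(meta[i, , drop = FALSE]))
    manifest[[i]] <- rec
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read trials written by [write_trials()]
#'
#' Validates the manifest against the CSV files: required columns, finite
#' values, and a strictly increasing constant-step time grid. Malformed
#' trials are reported by file name.
#'
#' @param dir Directory containing `manifest.json` and the trial CSVs.
#' @return A list of [trial_time_series()] objects, with any extra manifest
#'   fields attached as a `meta` attribute on each trial.
#' @export
read_trials <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (length(manifest) == 0) stop("empty manifest in ", dir)
  lapply(manifest, function(rec) {
    fpath <- file.path(dir, rec$file)
    if (!file.exists(fpath)) {
      stop("manifest names missing trial file: ", rec$file)
    }
    d <- utils::read.csv(fpath)
    need <- c("time_s", "left_pos", "right_pos")
    missing_cols <- setdiff(need, names(d))
    if (length(missing_cols)) {
      stop(sprintf("%s: missing columns %s", rec$file,
                   paste(missing_cols, collapse = ", ")))
    }
    bad <- which(!stats::complete.cases(d[need]) |
                   !is.finite(d$left_pos) | !is.finite(d$right_pos))
    if (length(bad)) {
      stop(sprintf("%s: malformed rows at lines %s", rec$file,
                   paste(utils::head(bad + 1, 5), collapse = ", ")))
    }
    if (any(diff(d$time_s) <= 0)) {
      stop(sprintf("%s: time_s is not strictly increasing", rec$file))
    }
    tr <- trial_time_series(time = d$time_s, left_position = d$left_pos,
                            right_position = d$right_pos,
                            target_phase = rec$target_phase,
                            session_index = rec$session_index,
                            trial_index = rec$trial_index,
                            sample_rate = rec$sample_rate)
    extra <- rec[setdiff(names(rec),
                         c("file", "target_phase", "session_index",
                           "trial_index", "sample_rate"))]
    if (length(extra)) attr(tr, "meta") <- extra
    tr
  })
}

#' Score a collection of trials into a tidy table
#'
#' @param trials List of [trial_time_series()] objects.
#' @param bandwidth Scoring bandwidth, degrees.
#' @param ... Passed to [score_trial()].
#' @return Data frame with one row per trial: `session_index`,
#'   `trial_index`, `target_phase`, `bandwidth`, `ptt`.
#' @export
score_trials <- function(trials, bandwidth = 20, ...) {
  rows <- lapply(trials, function(tr) {
    sc <- score_trial(tr, bandwidth = bandwidth, ...)
    data.frame(session_index = tr$session_index,
               trial_index = tr$trial_index,
               target_phase = tr$target_phase,
               bandwidth = bandwidth, ptt = sc$ptt)
  })
  do.call(rbind, rows)
}
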