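#' Write a trial recording (and optional ground truth) to disk
#'
#' One columnar CSV per trial (`<prefix>.csv`: time, sensor, axis, acc,
#' gyr) plus a JSON sidecar (`<prefix>.json`) holding press times, sensor
#' roles, sampling rate, and -- for simulated trials -- the ground truth.
#' Numbers are written at full precision so the round trip through
#' [read_trial()] is bit-exact.
#'
#' @param trial An `fm_trial`.
#' @param prefix File path prefix (without extension).
#' @param truth Optional `fm_ground_truth`.
#' @return Invisibly, the two file paths.
#' @export
write_trial <- function(trial, prefix, truth = NULL) {
  stopifnot(inherits(trial, "fm_trial"))
  d <- dim(trial$acc)
  n <- d[1]; n_sensors <- d[3]
  # numeric columns are rendered with 17 significant digits so the text
  # round-trips to bit-identical doubles
  long <- data.table::data.table(
    time = sprintf("%.17g", rep((seq_len(n) - 1) / trial$fs, times = 3L * n_sensors)),
    sensor = rep(rep(seq_len(n_sensors), each = 3L * n), 1L),
    axis = rep(rep(c("x", "y", "z"), each = n), times = n_sensors),
    acc = sprintf("%.17g", as.vector(trial$acc)),
    gyr = sprintf("%.17g", as.vector(trial$gyr))
  )
  csv_path <- paste0(prefix, ".csv")
  json_path <- paste0(prefix, ".json")
  data.table::fwrite(long, csv_path)
  side <- list(
    fs = trial$fs, duration = trial$duration,
    press_times = trial$press_times,
    sensor_roles = trial$sensor_roles
  )
  if (!is.null(truth)) {
    side$ground_truth <- list(
      event_onsets = truth$event_onsets,
      event_durations = truth$event_durations,
      event_sensors = truth$event_sensors,
      perceived = truth$perceived,
      reaction_delays = truth$reaction_delays,
      press_times = truth$press_times
    )
  }
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a trial recording written by [write_trial()]
#'
#' @param prefix File path prefix used at write time.
#' @return A list with `trial` (class `fm_trial`) and `truth` (class
#'   `fm_ground_truth`, or `NULL` if no ground truth was stored).
#' @export
read_trial <- function(prefix) {
  long <- data.table::fread(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n_sensors <- max(long$sensor)
  n <- nrow(long) / (3L * n_sensors)
  acc <- array(long$acc, dim = c(n, 3L, n_sensors))
  gyr <- array(long$gyr, dim = c(n, 3L, n_sensors))
  trial <- structure(list(
    acc = acc, gyr = gyr, fs = side$fs, duration = side$duration,
    press_times = as.numeric(side$press_times %||% numeric(0)),
    sensor_roles = list(
      abdominal = as.integer(side$sensor_roles$abdominal),
      reference = as.integer(side$sensor_roles$reference)),
    mounting = NULL), class = "fm_trial")
  truth <- NULL
  if (!is.null(side$ground_truth)) {
    gt <- side$ground_truth
    # footprints are parsed from the unsimplified JSON: simplifyVector
    # would collapse a list of equal-length footprints into a matrix
    raw <- jsonlite::read_json(paste0(prefix, ".json"))
    truth <- structure(list(
      event_onsets = as.numeric(gt$event_onsets %||% numeric(0)),
      event_durations = as.numeric(gt$event_durations %||% numeric(0)),
      event_sensors = lapply(raw$ground_truth$event_sensors,
                             function(v) as.integer(unlist(v))),
      perceived = as.logical(gt$perceived %||% logical(0)),
      reaction_delays = as.numeric(gt$reaction_delays %||% numeric(0)),
      press_times = as.numeric(gt$press_times %||% numeric(0))),
      class = "fm_ground_truth")
  }
  list(trial = trial, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write window labels as CSV
#'
#' @param grid An `fm_grid`.
#' @param labels Integer labels, one per window.
#' @param trial_id Identifier recorded in the `trial_id` column.
#' @param path Output CSV path.
#' @return Invisibly, the label table that was written.
#' @export
write_labels <- function(grid, labels, trial_id, path) {
  tab <- data.frame(trial_id = trial_id,
                    window_start_s = grid$start_s,
                    window_len_s = grid$n_window_samples / attr(grid, "fs"),
                    label = as.integer(labels))
  data.table::fwrite(tab, path)
  invisible(tab)
}

# Polynomial rolling hash of a configuration's deparsed form, for
# provenance stamping of derived artifacts (all arithmetic stays exact in
# doubles: h < 2^32 and h*131 + b < 2^53).
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 4294967291
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Read or write an experiment configuration as YAML
#'
#' A run is reproducible from its archived configuration and seed; these
#' helpers round-trip the configuration list through a human-readable
#' YAML file (matrices such as mounting rotations are not serialized).
#'
#' @param config An `fm_experiment_config` (see [experiment_config()]).
#' @param path YAML file path.
#' @return `write_run_config()` the path, invisibly;
#'   `read_run_config()` the restored configuration.
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$sim <- unclass(plain$sim)
  plain$sim$mounting_rotations <- NULL
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  plain <- yaml::read_yaml(path)
  sim_args <- plain$sim
  sim_args$event_band <- as.numeric(unlist(sim_args$event_band))
  plain$sim <- do.call(sim_config, sim_args)
  do.call(experiment_config, plain[setdiff(names(plain), character(0))])
}
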