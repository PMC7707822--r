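#' Session configuration
#'
#' One flat bag of per-recording settings: treadmill/corridor geometry,
#' camera calibration, and every analysis parameter a session run needs.
#' Parameters not listed explicitly can be supplied through `...` and are
#' stored verbatim (they override the defaults below when names collide).
#'
#' Defaults follow the package-wide conventions: times in seconds,
#' positions in cm, rates in Hz.
#'
#' @param belt_speed treadmill belt speed in cm/s; 0 for overground.
#' @param incline_pct treadmill incline in percent.
#' @param px_per_cm camera calibration (pixels per cm), > 0.
#' @param condition free-text condition label.
#' @param context `"treadmill"` or `"airpuff"`; selects the minimum breath
#'   count for a valid orientation verdict (35 vs 20).
#' @param fps video frame rate in Hz.
#' @param baseline_epoch numeric `c(start, end)` in s: pre-run control
#'   epoch used for amplitude normalization (and, absent `noise_epoch`,
#'   the detection threshold).
#' @param noise_epoch numeric `c(start, end)` in s: a user-marked stretch
#'   of expiratory silence used for the robust detection threshold.
#' @param run_epoch numeric `c(start, end)` in s: the running bout.
#' @param ... further analysis parameters; see Details.
#' @details Recognised analysis parameters and defaults:
#' `integration_window` (0.015 s), `k_mad` (5), `hysteresis_frac` (0.5),
#' `min_Ti` (0.02 s), `merge_gap` (0.005 s), `window_s` (6), `n_windows` (3),
#' `skip_s` (20), `likelihood_min` (0.9), `median_window` (3 frames),
#' `vel_window` (0.015 s), `stance_frac` (0.25), `min_stance` (0.025 s),
#' `min_swing` (0.025 s), `gait_tol` (0.15), `stable_win` (1 s),
#' `stable_max_sd` (1 cm), `stable_max_drift` (2 cm/s), `resample_fs`
#' (1000 Hz), `R_threshold` (0.3), `n_bins` (10).
#' @return An object of class `session_config` (a named list).
#' @export
session_config <- function(belt_speed = 0, incline_pct = 0, px_per_cm = 1,
                           condition = "unspecified", context = "treadmill",
                           fps = 200, baseline_epoch = NULL, run_epoch = NULL,
                           noise_epoch = NULL, ...) {
  defaults <- list(
    integration_window = 0.015, k_mad = 5, hysteresis_frac = 0.5,
    min_Ti = 0.02, merge_gap = 0.005,
    window_s = 6, n_windows = 3, skip_s = 20,
    likelihood_min = 0.9, median_window = 3,
    vel_window = 0.015, stance_frac = 0.25, min_stance = 0.025,
    min_swing = 0.025, gait_tol = 0.15,
    stable_win = 1, stable_max_sd = 1, stable_max_drift = 2,
    resample_fs = 1000, R_threshold = 0.3, n_bins = 10
  )
  extra <- list(...)
  params <- utils::modifyList(defaults, extra)
  cfg <- c(list(belt_speed = belt_speed, incline_pct = incline_pct,
                px_per_cm = px_per_cm, condition = condition,
                context = context, fps = fps,
                baseline_epoch = baseline_epoch, run_epoch = run_epoch,
                noise_epoch = noise_epoch),
           params)
  validate_session_config(cfg)
}

validate_session_config <- function(cfg) {
  if (!is_scalar_num(cfg$px_per_cm) || cfg$px_per_cm <= 0)
    stop_config("px_per_cm must be > 0")
  if (!is_scalar_num(cfg$belt_speed) || cfg$belt_speed < 0)
    stop_config("belt_speed must be >= 0")
  if (!cfg$context %in% c("treadmill", "airpuff"))
    stop_config("context must be 'treadmill' or 'airpuff', got '%s'", cfg$context)
  for (ep in c("baseline_epoch", "run_epoch", "noise_epoch")) {
    e <- cfg[[ep]]
    if (!is.null(e) && (length(e) != 2L || !all(is.finite(e)) || e[2L] <= e[1L]))
      stop_config("%s must be c(start, end) with end > start", ep)
  }
  structure(cfg, class = "session_config")
}

#' Read a session configuration from YAML
#'
#' Flat key: value YAML; keys are passed to [session_config()], so unknown
#' keys become analysis parameters and known keys override the defaults.
#' Epochs are written as two-element sequences.
#'
#' @param path YAML file path.
#' @return a `session_config`.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_format("bad YAML in %s: %s", path, conditionMessage(e)))
  if (!is.list(raw)) stop_format("config %s must be a YAML mapping", path)
  do.call(session_config, raw)
}

#' Write a session configuration to YAML
#' @param cfg a `session_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "session_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
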