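# Diaphragm EMG processing: envelope extraction, inspiratory burst
# detection, and per-cycle respiratory parameters. One inspiratory burst is
# one bout of diaphragm activity; Ti is its duration, Te the silence until
# the next bout, and 1/(Ti+Te) the instantaneous respiratory frequency.

#' Integrate an EMG trace (moving RMS envelope)
#'
#' Centered moving root-mean-square over a window of `window` seconds.
#' The window length in samples is rounded and forced odd (one sample is
#' added to an even count) so the window is symmetric; near the edges the
#' window shrinks symmetrically.
#'
#' @param raw a `loco_ts` with the raw EMG.
#' @param window window length in seconds; must span at least 2 samples.
#' @return a `loco_ts` of the same length, fs and t0.
#' @export
integrate_emg <- function(raw, window = 0.015) {
  stopifnot(inherits(raw, "loco_ts"))
  n_win <- round(window * raw$fs)
  if (!is_scalar_num(window) || n_win < 2)
    stop_parameter("integration window must span at least 2 samples (got %g s at %g Hz)",
                   window, raw$fs)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  h <- (n_win - 1L) / 2L
  v <- raw$values
  n <- length(v)
  cs <- cumsum(c(0, v * v))
  i <- seq_len(n)
  hw <- pmin(h, i - 1L, n - i)
  out <- sqrt((cs[i + hw + 1L] - cs[i - hw]) / (2 * hw + 1))
  time_series(out, raw$fs, raw$t0)
}

#' Burst-detection configuration
#'
#' @param threshold_mode `"robust-baseline"` (threshold from a quiet epoch:
#'   median + `k_mad` * MAD of the integrated signal) or `"absolute"`
#'   (fixed `threshold`).
#' @param threshold absolute upper threshold (integrated-signal units);
#'   required when `threshold_mode = "absolute"`.
#' @param k_mad MAD multiplier for the robust threshold.
#' @param hysteresis_frac lower threshold as a fraction of the upper one,
#'   in (0, 1]. A burst opens when the envelope reaches the upper threshold
#'   and closes when it falls below the lower one.
#' @param min_Ti minimum burst duration in s; shorter bursts are discarded.
#' @param merge_gap bursts separated by a silent gap shorter than this (s)
#'   are merged.
#' @param integration_window envelope RMS window in s (kept with the
#'   detection settings so one object documents the whole detection).
#' @return an object of class `burst_detect_config`.
#' @export
burst_detect_config <- function(threshold_mode = c("robust-baseline", "absolute"),
                                threshold = NULL, k_mad = 5,
                                hysteresis_frac = 0.5, min_Ti = 0.02,
                                merge_gap = 0.005, integration_window = 0.015) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "absolute" &&
      (!is_scalar_num(threshold) || threshold <= 0))
    stop_parameter("absolute mode needs a positive threshold")
  if (!is_scalar_num(hysteresis_frac) || hysteresis_frac <= 0 || hysteresis_frac > 1)
    stop_parameter("hysteresis_frac must be in (0, 1]")
  if (!is_scalar_num(min_Ti) || min_Ti < 0) stop_parameter("min_Ti must be >= 0")
  if (!is_scalar_num(merge_gap) || merge_gap < 0) stop_parameter("merge_gap must be >= 0")
  if (!is_scalar_num(integration_window) || integration_window <= 0)
    stop_parameter("integration_window must be > 0")
  structure(list(threshold_mode = threshold_mode, threshold = threshold,
                 k_mad = k_mad, hysteresis_frac = hysteresis_frac,
                 min_Ti = min_Ti, merge_gap = merge_gap,
                 integration_window = integration_window),
            class = "burst_detect_config")
}

#' Detect inspiratory bursts in an integrated EMG trace
#'
#' Threshold search with hysteresis: a burst is the maximal interval that
#' starts when the envelope first reaches the upper threshold and ends when
#' it falls below the lower threshold (`hysteresis_frac` x upper). Bursts
#' separated by gaps shorter than `merge_gap` are merged, then bursts
#' shorter than `min_Ti` discarded. `peak_amp` is the envelope maximum
#' within the burst.
#'
#' @param integrated a `loco_ts` (output of [integrate_emg()]).
#' @param cfg a [burst_detect_config()].
#' @param baseline_epoch `c(start, end)` in s; required in robust-baseline
#'   mode (upper threshold = median + k_mad * MAD over this epoch).
#' @return data frame with columns `onset`, `offset`, `peak_amp` (s, s,
#'   envelope units); zero rows when nothing crosses the threshold. The
#'   upper threshold used is attached as attribute `"threshold"`.
#' @export
detect_bursts <- function(integrated, cfg = burst_detect_config(),
                          baseline_epoch = NULL) {
  stopifnot(inherits(integrated, "loco_ts"), inherits(cfg, "burst_detect_config"))
  v <- integrated$values; fs <- integrated$fs; t0 <- integrated$t0
  if (cfg$threshold_mode == "absolute") {
    upper <- cfg$threshold
    lower <- cfg$hysteresis_frac * upper
  } else {
    if (is.null(baseline_epoch))
      stop_parameter("robust-baseline mode needs a baseline_epoch")
    tt <- t0 + (seq_along(v) - 1L) / fs
    base <- v[tt >= baseline_epoch[1L] & tt < baseline_epoch[2L]]
    if (!length(base)) stop_parameter("baseline_epoch contains no samples")
    med <- stats::median(base)
    upper <- med + cfg$k_mad * stats::mad(base)
    # the RMS envelope has a nonzero noise floor (~ the baseline median),
    # so hysteresis applies to the supra-baseline elevation; with a zero
    # floor this reduces to lower = frac * upper
    lower <- med + cfg$hysteresis_frac * (upper - med)
  }

  empty <- data.frame(onset = numeric(0), offset = numeric(0), peak_amp = numeric(0))
  above_l <- v >= lower
  if (!any(v >= upper)) return(structure(empty, threshold = upper))

  # maximal runs above the lower threshold; a run is a burst iff it touches
  # the upper threshold. Hysteresis is applied to both edges: the burst is
  # the whole above-lower run (with hysteresis_frac = 1 this reduces to a
  # plain super-threshold run scan).
  r <- rle(above_l)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- integer(0); off <- integer(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    if (any(v[seg] >= upper)) { on <- c(on, starts[k]); off <- c(off, ends[k]) }
  }
  # sample i (1-based) covers [t0+(i-1)/fs, t0+i/fs): onset at interval
  # start of the first super-threshold sample, offset at interval end of
  # the last supra-lower sample
  onset  <- t0 + (on - 1L) / fs
  offset <- t0 + off / fs

  if (length(onset) > 1L && cfg$merge_gap > 0) {
    m_on <- numeric(0); m_off <- numeric(0)
    cur_on <- onset[1L]; cur_off <- offset[1L]
    for (j in seq_along(onset)[-1L]) {
      if (onset[j] - cur_off < cfg$merge_gap) {
        cur_off <- offset[j]
      } else {
        m_on <- c(m_on, cur_on); m_off <- c(m_off, cur_off)
        cur_on <- onset[j]; cur_off <- offset[j]
      }
    }
    onset <- c(m_on, cur_on); offset <- c(m_off, cur_off)
  }

  keep <- (offset - onset) >= cfg$min_Ti
  onset <- onset[keep]; offset <- offset[keep]
  if (!length(onset)) return(structure(empty, threshold = upper))

  peak <- vapply(seq_along(onset), function(j) {
    i0 <- floor((onset[j] - t0) * fs) + 1L
    i1 <- ceiling((offset[j] - t0) * fs)
    max(v[max(1L, i0):min(length(v), i1)])
  }, 1.0)
  structure(data.frame(onset = onset, offset = offset, peak_amp = peak),
            threshold = upper)
}

#' Derive respiratory cycles from detected bursts
#'
#' Each consecutive burst pair defines one cycle: `Ti` is the burst
#' duration, `Te` the silence until the next onset, and
#' `f_inst = 1/(Ti + Te)`. The last burst opens no cycle.
#'
#' @param bursts data frame from [detect_bursts()].
#' @return data frame with columns `onset`, `Ti`, `Te`, `f_inst`,
#'   `peak_amp`; zero rows (with a message) for fewer than 2 bursts.
#' @export
respiratory_cycles <- function(bursts) {
  stopifnot(is.data.frame(bursts))
  if (nrow(bursts) < 2L) {
    message("respiratory_cycles: fewer than 2 bursts, no cycles")
    return(data.frame(onset = numeric(0), Ti = numeric(0), Te = numeric(0),
                      f_inst = numeric(0), peak_amp = numeric(0)))
  }
  n <- nrow(bursts)
  Ti <- bursts$offset[-n] - bursts$onset[-n]
  Te <- bursts$onset[-1L] - bursts$offset[-n]
  if (any(Te <= 0)) stop_validation("overlapping or unordered bursts")
  data.frame(onset = bursts$onset[-n], Ti = Ti, Te = Te,
             f_inst = 1 / (Ti + Te), peak_amp = bursts$peak_amp[-n])
}

#' Normalize burst amplitudes to a pre-run baseline
#'
#' @param cycles data frame of respiratory cycles (needs `peak_amp`).
#' @param baseline_cycles non-empty data frame of control cycles recorded
#'   before running started.
#' @return numeric vector: each cycle's peak amplitude as a percent of the
#'   mean baseline peak amplitude.
#' @export
normalize_amplitude <- function(cycles, baseline_cycles) {
  if (!is.data.frame(baseline_cycles) || nrow(baseline_cycles) == 0L)
    stop_parameter("baseline_cycles must be non-empty")
  100 * cycles$peak_amp / mean(baseline_cycles$peak_amp)
}

#' Select measurement windows within a running epoch and summarise cycles
#'
#' Respiratory parameters are measured over a few fixed-length windows
#' placed inside the run, skipping its first `skip_s` seconds (stress
#' transient); the per-session value of each parameter is the mean of the
#' per-window means. Window placement is deterministic: `n_windows`
#' non-overlapping windows evenly spaced over the admissible span (fewer
#' when the span is short; a single truncated window, flagged with
#' `warning = TRUE`, when not even one full window fits).
#'
#' @param cycles data frame of respiratory cycles (`onset`, `Ti`, `Te`,
#'   `f_inst`, `peak_amp`); a cycle belongs to a window when its onset
#'   falls inside it.
#' @param run_epoch `c(start, end)` of the running bout in s.
#' @param window_s window length in s.
#' @param n_windows desired number of windows.
#' @param skip_s seconds skipped at the start of the run.
#' @return list with `windows` (data frame: `start`, `end`, `n_cycles`,
#'   `f`, `Ti`, `Te`, `amp`), `summary` (named means over windows) and
#'   `warning` (logical: epoch shorter than skip + one window).
#' @export
select_measurement_windows <- function(cycles, run_epoch, window_s = 6,
                                       n_windows = 3, skip_s = 20) {
  if (length(run_epoch) != 2L || run_epoch[2L] <= run_epoch[1L])
    stop_parameter("run_epoch must be c(start, end), end > start")
  s0 <- run_epoch[1L] + skip_s
  L <- run_epoch[2L] - s0
  warn <- FALSE
  if (L <= 0) {
    warn <- TRUE
    s0 <- run_epoch[1L]; L <- run_epoch[2L] - run_epoch[1L]
  }
  k <- min(n_windows, floor(L / window_s))
  if (k < 1L) {
    warn <- TRUE
    starts <- s0; ends <- run_epoch[2L]
  } else if (k == 1L) {
    starts <- s0; ends <- s0 + window_s
  } else {
    starts <- s0 + (seq_len(k) - 1L) * (L - window_s) / (k - 1L)
    ends <- starts + window_s
  }
  rows <- lapply(seq_along(starts), function(j) {
    sel <- cycles$onset >= starts[j] & cycles$onset < ends[j]
    cc <- cycles[sel, , drop = FALSE]
    data.frame(start = starts[j], end = ends[j], n_cycles = nrow(cc),
               f = mean(cc$f_inst), Ti = mean(cc$Ti), Te = mean(cc$Te),
               amp = mean(cc$peak_amp))
  })
  win <- do.call(rbind, rows)
  nonempty <- win$n_cycles > 0L
  summ <- c(f = mean(win$f[nonempty]), Ti = mean(win$Ti[nonempty]),
            Te = mean(win$Te[nonempty]), amp = mean(win$amp[nonempty]))
  list(windows = win, summary = summ, warning = warn)
}
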