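# Gait kinematics: clean pose tracks, segment each limb's forward motion
# into footfall-delimited stride cycles with stance/swing phases, classify
# the gait from interlimb phasing, find stable running epochs from the head
# trace, and compute open-field mobility metrics.

.odd_window <- function(w_s, fs, minimum = 1L) {
  n <- max(minimum, round(w_s * fs))
  if (n %% 2 == 0) n <- n + 1L
  as.integer(n)
}

#' Clean a pose track
#'
#' Frames with tracking likelihood below `likelihood_min` get x and y
#' replaced by linear interpolation between the nearest valid neighbours
#' (edge gaps hold the nearest valid value); both coordinates are then
#' passed through an odd-length running median. Likelihood is unchanged.
#'
#' @param track a `pose_track`.
#' @param likelihood_min validity threshold in `[0, 1]`.
#' @param median_window running-median window in frames (odd; 1 = no
#'   median filtering).
#' @return a cleaned `pose_track`.
#' @export
clean_pose <- function(track, likelihood_min = 0.9, median_window = 3) {
  stopifnot(inherits(track, "pose_track"))
  ok <- track$likelihood >= likelihood_min
  if (!any(ok))
    stop_validation("all %d frames of %s below likelihood %g",
                    length(ok), track$bodypart, likelihood_min)
  fix <- function(z) {
    if (all(ok)) return(z)
    stats::approx(which(ok), z[ok], xout = seq_along(z), rule = 2)$y
  }
  x <- fix(track$x); y <- fix(track$y)
  if (median_window > 1) {
    if (median_window %% 2 == 0) stop_parameter("median_window must be odd")
    x <- as.numeric(stats::runmed(x, median_window))
    y <- as.numeric(stats::runmed(y, median_window))
  }
  pose_track(track$bodypart, x, y, track$likelihood, track$fps)
}

#' Resample a pose track onto a uniform higher-rate grid
#'
#' Linear interpolation of x and y onto a grid at `fs_target` spanning the
#' original record (first to last frame time).
#'
#' @param track a `pose_track` (clean it first).
#' @param fs_target target rate in Hz, >= the track's fps.
#' @return list with elements `x` and `y`, each a `loco_ts` at `fs_target`.
#' @export
resample_track <- function(track, fs_target) {
  stopifnot(inherits(track, "pose_track"))
  if (!is_scalar_num(fs_target) || fs_target < track$fps)
    stop_parameter("fs_target (%g) must be >= track fps (%g)", fs_target, track$fps)
  n <- length(track$x)
  t_orig <- (seq_len(n) - 1L) / track$fps
  n_out <- floor(t_orig[n] * fs_target) + 1L
  t_new <- (seq_len(n_out) - 1L) / fs_target
  xi <- stats::approx(t_orig, track$x, xout = t_new, rule = 2)$y
  yi <- stats::approx(t_orig, track$y, xout = t_new, rule = 2)$y
  list(x = time_series(xi, fs_target), y = time_series(yi, fs_target))
}

# collapse runs shorter than their minimum duration into the neighbouring
# state, shortest offender first
.absorb_short_runs <- function(state, fs, min_stance, min_swing) {
  repeat {
    r <- rle(state)
    if (length(r$lengths) <= 1L) return(state)
    dur <- r$lengths / fs
    minima <- ifelse(r$values, min_stance, min_swing)
    # never absorb the terminal runs: their true extent is censored
    bad <- which(dur < minima)
    bad <- bad[bad != 1L & bad != length(r$lengths)]
    if (!length(bad)) return(state)
    j <- bad[which.min(dur[bad])]
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    state[starts[j]:ends[j]] <- !r$values[j]
  }
}

#' Segment a paw's forward motion into stride cycles
#'
#' Velocity-threshold footfall detection. Forward velocity is estimated by
#' central differences smoothed over `vel_window`. On a treadmill
#' (`belt_speed > 0`) the camera frame moves with the body, so a paw in
#' stance travels backward with the belt: stance is where velocity
#' `< -stance_frac * belt_speed`. Overground, stance is where the
#' world-frame speed is `< stance_frac * v_ref` (pass the smoothed body
#' speed as `v_ref`). Stance/swing runs shorter than `min_stance` /
#' `min_swing` are absorbed into their neighbour. Footfall = swing-to-stance
#' transition (touch-down); liftoff = stance-to-swing. Consecutive footfalls
#' of the limb delimit one stride cycle.
#'
#' @param x `loco_ts` of the paw's forward position in cm (camera frame).
#' @param belt_speed treadmill belt speed in cm/s; 0 for overground.
#' @param v_ref reference speed in cm/s for overground recordings.
#' @param vel_window velocity smoothing window in s.
#' @param stance_frac stance threshold as a fraction of the reference speed.
#' @param min_stance,min_swing minimum run durations in s.
#' @param limb limb label attached to the cycles.
#' @return data frame with columns `limb`, `footfall_prev`, `liftoff`,
#'   `footfall_next`, `duty` (zero rows, with a message, when fewer than
#'   2 footfalls are found). Footfall times are attached as attribute
#'   `"footfalls"`, liftoffs as `"liftoffs"`.
#' @export
detect_stance_swing <- function(x, belt_speed, v_ref = NULL,
                                vel_window = 0.015, stance_frac = 0.25,
                                min_stance = 0.025, min_swing = 0.025,
                                limb = NA_character_) {
  stopifnot(inherits(x, "loco_ts"))
  treadmill <- !is.null(belt_speed) && belt_speed > 0
  if (treadmill) {
    vref <- belt_speed
  } else {
    if (is.null(v_ref) || !is_scalar_num(v_ref) || v_ref <= 0)
      stop_parameter("overground segmentation needs a positive v_ref")
    vref <- v_ref
  }
  v <- x$values; n <- length(v); fs <- x$fs
  if (n < 5L) stop_parameter("trace too short for velocity estimation")
  vel <- c(v[2L] - v[1L], (v[3:n] - v[1:(n - 2L)]) / 2, v[n] - v[n - 1L]) * fs
  nw <- .odd_window(vel_window, fs)
  if (nw > 1L) {
    k <- rep(1 / nw, nw)
    vel <- as.numeric(stats::filter(vel, k, sides = 2))
    h <- (nw - 1L) / 2L
    vel[seq_len(h)] <- vel[h + 1L]
    vel[(n - h + 1L):n] <- vel[n - h]
  }
  stance <- if (treadmill) vel < -stance_frac * vref else abs(vel) < stance_frac * vref
  empty <- data.frame(limb = character(0), footfall_prev = numeric(0),
                      liftoff = numeric(0), footfall_next = numeric(0),
                      duty = numeric(0))
  if (!any(stance) || all(stance)) {
    message("detect_stance_swing: no stance/swing alternation found")
    return(structure(empty, footfalls = numeric(0), liftoffs = numeric(0)))
  }
  stance <- .absorb_short_runs(stance, fs, min_stance, min_swing)
  d <- diff(stance)
  ff_i <- which(d == 1L) + 1L   # first stance frame
  lo_i <- which(d == -1L) + 1L  # first swing frame
  tt <- ts_times(x)
  # sub-sample refinement: smoothing turns the velocity step at
  # touch-down/lift-off into a ramp whose acceleration pulse is symmetric
  # about the true event, so the event time is the centroid of the
  # sign-appropriate acceleration near the transition (touch-down
  # decelerates the paw's forward motion, lift-off accelerates it);
  # opposite-sign neighbouring pulses carry zero weight, so the window can
  # exceed the smoothing width without contamination. The raw threshold
  # crossing is biased toward the later plateau.
  W <- (nw - 1L) %/% 2L + as.integer(round(0.01 * fs)) + 2L
  acc <- c(diff(vel), 0)
  refine <- function(i, sgn) {
    j0 <- max(1L, i - W); j1 <- min(n - 1L, i + W)
    w <- pmax(0, sgn * acc[j0:j1])
    if (sum(w) <= 0) return(tt[i])
    sum(tt[j0:j1] * w) / sum(w) + 0.5 / fs
  }
  footfalls <- vapply(ff_i, refine, 1.0, sgn = -1)
  liftoffs <- vapply(lo_i, refine, 1.0, sgn = 1)
  if (length(footfalls) < 2L) {
    message("detect_stance_swing: fewer than 2 footfalls")
    return(structure(empty, footfalls = footfalls, liftoffs = liftoffs))
  }
  cyc <- lapply(seq_len(length(footfalls) - 1L), function(k) {
    lo <- liftoffs[liftoffs > footfalls[k] & liftoffs < footfalls[k + 1L]]
    if (length(lo) != 1L) return(NULL)
    data.frame(limb = limb, footfall_prev = footfalls[k], liftoff = lo,
               footfall_next = footfalls[k + 1L],
               duty = (lo - footfalls[k]) / (footfalls[k + 1L] - footfalls[k]))
  })
  out <- do.call(rbind, Filter(Negate(is.null), cyc))
  if (is.null(out)) out <- empty
  structure(out, footfalls = footfalls, liftoffs = liftoffs)
}

.circ_dist <- function(a, b) {
  d <- abs((a - b) %% 1)
  pmin(d, 1 - d)
}

#' Mean relative phase between two footfall trains
#'
#' Each footfall of limb B is assigned a phase within its enclosing limb-A
#' cycle (0 at the preceding A footfall, 1 at the next); the circular mean
#' of those phases is returned in `[0, 1)`.
#'
#' @param footfalls_a,footfalls_b footfall times in s, at least 3 each.
#' @return scalar mean relative phase in `[0, 1)`.
#' @export
relative_phase <- function(footfalls_a, footfalls_b) {
  if (length(footfalls_a) < 3L || length(footfalls_b) < 3L)
    stop_parameter("need at least 3 footfalls per limb")
  strides <- data.frame(limb = "A",
                        footfall_prev = footfalls_a[-length(footfalls_a)],
                        liftoff = NA_real_,
                        footfall_next = footfalls_a[-1L])
  k <- findInterval(footfalls_b, strides$footfall_prev)
  ok <- k >= 1L & footfalls_b < strides$footfall_next[pmax(k, 1L)]
  if (!any(ok)) stop_parameter("no B footfalls inside A cycles")
  phi <- (footfalls_b[ok] - strides$footfall_prev[k[ok]]) /
    (strides$footfall_next[k[ok]] - strides$footfall_prev[k[ok]])
  z <- mean(exp(2i * pi * phi))
  (Arg(z) / (2 * pi)) %% 1
}

#' Classify the gait from interlimb relative phases
#'
#' Trot: the homologous hindlimbs alternate (hind relative phase near 0.5).
#' Gallop: hindlimbs synchronized (hind phase near 0) with forelimbs
#' alternating (fore phase near 0.5). Anything else is `undetermined`.
#' Nearness is circular distance within `tol`.
#'
#' @param hind_rel_phase,fore_rel_phase relative phases in `[0, 1)` of the
#'   left vs right hindlimb and forelimb footfall trains.
#' @param tol circular tolerance around the target phases.
#' @return list with `label` (`"trot"`, `"gallop"` or `"undetermined"`),
#'   `hind_rel_phase`, `fore_rel_phase`.
#' @export
classify_gait <- function(hind_rel_phase, fore_rel_phase, tol = 0.15) {
  stopifnot(is_scalar_num(hind_rel_phase), is_scalar_num(fore_rel_phase))
  label <- if (.circ_dist(hind_rel_phase, 0.5) <= tol) {
    "trot"
  } else if (.circ_dist(hind_rel_phase, 0) <= tol &&
             .circ_dist(fore_rel_phase, 0.5) <= tol) {
    "gallop"
  } else "undetermined"
  list(label = label, hind_rel_phase = hind_rel_phase,
       fore_rel_phase = fore_rel_phase)
}

#' Find stable running epochs from the head trace
#'
#' A running animal keeping pace with the belt shows no net change in the
#' head's horizontal coordinate. A sliding window of `win` seconds is
#' stable iff the SD of head x is at most `max_sd` and the absolute slope
#' of a linear fit is at most `max_drift`; overlapping stable windows are
#' merged into maximal epochs.
#'
#' @param head_x `loco_ts` of the calibrated head x coordinate (cm).
#' @param win window length in s.
#' @param max_sd maximum within-window SD in cm.
#' @param max_drift maximum linear drift in cm/s.
#' @param step_frac window step as a fraction of `win`.
#' @return data frame with columns `start`, `end`, `label`
#'   (`"stable"`/`"unstable"`), ordered, non-overlapping, covering the
#'   record.
#' @export
stable_epochs <- function(head_x, win = 1, max_sd = 1, max_drift = 2,
                          step_frac = 0.1) {
  stopifnot(inherits(head_x, "loco_ts"))
  fs <- head_x$fs; v <- head_x$values; n <- length(v)
  wlen <- round(win * fs)
  t_end <- head_x$t0 + n / fs
  if (wlen < 2L || n < wlen) {
    warning("record shorter than the stability window; all unstable")
    return(data.frame(start = head_x$t0, end = t_end, label = "unstable"))
  }
  step <- max(1L, round(step_frac * wlen))
  starts_i <- unique(c(seq(1L, n - wlen + 1L, by = step), n - wlen + 1L))
  # rolling first/second moments and slope via cumulative sums
  cs1 <- cumsum(c(0, v)); cs2 <- cumsum(c(0, v * v))
  csx <- cumsum(c(0, v * seq_len(n)))
  i2 <- starts_i + wlen - 1L
  s1 <- cs1[i2 + 1L] - cs1[starts_i]
  s2 <- cs2[i2 + 1L] - cs2[starts_i]
  sx <- csx[i2 + 1L] - csx[starts_i]
  m <- s1 / wlen
  sdv <- sqrt(pmax(0, (s2 - wlen * m^2) / (wlen - 1L)))
  ibar <- (starts_i + i2) / 2
  sii <- wlen * (wlen^2 - 1) / 12          # sum (i - ibar)^2 for a length-wlen run
  slope <- (sx - s1 * ibar) / sii * fs     # cm per second
  ok <- sdv <= max_sd & abs(slope) <= max_drift
  tt0 <- head_x$t0
  ws <- tt0 + (starts_i - 1L) / fs
  we <- tt0 + i2 / fs
  # merge overlapping stable windows
  stable <- data.frame(start = numeric(0), end = numeric(0))
  if (any(ok)) {
    s <- ws[ok]; e <- we[ok]
    cur_s <- s[1L]; cur_e <- e[1L]
    for (j in seq_along(s)[-1L]) {
      if (s[j] <= cur_e) cur_e <- max(cur_e, e[j])
      else { stable <- rbind(stable, data.frame(start = cur_s, end = cur_e))
             cur_s <- s[j]; cur_e <- e[j] }
    }
    stable <- rbind(stable, data.frame(start = cur_s, end = cur_e))
  }
  # fill gaps with unstable epochs
  out <- data.frame(start = numeric(0), end = numeric(0), label = character(0))
  cursor <- tt0
  for (j in seq_len(nrow(stable))) {
    if (stable$start[j] > cursor)
      out <- rbind(out, data.frame(start = cursor, end = stable$start[j],
                                   label = "unstable"))
    out <- rbind(out, data.frame(start = stable$start[j], end = stable$end[j],
                                 label = "stable"))
    cursor <- stable$end[j]
  }
  if (cursor < t_end)
    out <- rbind(out, data.frame(start = cursor, end = t_end, label = "unstable"))
  out
}

#' Open-field mobility metrics
#'
#' Frame speed is the smoothed inter-frame displacement times the frame
#' rate. Mobility rate is the percent of frames with speed above
#' `mobility_speed_min`; mobility speed the mean speed over those frames
#' (NA when the animal never moves above threshold); distance the sum of
#' raw frame displacements.
#'
#' @param x,y trajectory coordinates in cm, one point per frame.
#' @param fps frame rate in Hz.
#' @param mobility_speed_min mobility threshold in cm/s.
#' @param smooth_window displacement smoothing window in frames (odd).
#' @return list with `mobility_rate` (percent), `mobility_speed` (cm/s or
#'   NA), `distance` (cm).
#' @export
open_field_metrics <- function(x, y, fps, mobility_speed_min = 7.5,
                               smooth_window = 5) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_parameter("need at least 2 frames with equal-length x and y")
  disp <- sqrt(diff(x)^2 + diff(y)^2)
  sm <- disp
  nw <- smooth_window
  if (nw %% 2 == 0) nw <- nw + 1L
  if (nw > 1L && length(disp) > nw) {
    sm <- as.numeric(stats::filter(disp, rep(1 / nw, nw), sides = 2))
    h <- (nw - 1L) / 2L
    sm[seq_len(h)] <- sm[h + 1L]
    sm[(length(sm) - h + 1L):length(sm)] <- sm[length(sm) - h]
  }
  speed <- sm * fps
  moving <- speed > mobility_speed_min
  list(mobility_rate = 100 * mean(moving),
       mobility_speed = if (any(moving)) mean(speed[moving]) else NA_real_,
       distance = sum(disp))
}
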