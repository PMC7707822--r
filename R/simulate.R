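# Synthetic locomotor-respiratory sessions with known ground truth.
#
# Gait: each limb shares one jittered master stride oscillator, offset by a
# gait-specific phase (trot: diagonal pairs together, homologous pairs in
# antiphase; gallop: hindlimbs together, forelimbs alternating). In the
# treadmill camera frame a stance paw travels backward with the belt and
# swings forward in between, giving the characteristic sawtooth x-trace;
# the vertical coordinate gets a half-sine swing lift.
#
# Breathing: inspiration onsets are drawn from a hazard process whose rate
# is modulated by a von Mises kernel of the reference limb's stride phase,
#   lambda(t) = lambda0 * exp(kappa * cos(2*pi*(phi(t) - mu))) / I0(kappa),
# with an absolute refractory period of 0.6 of the mean breath cycle.
# kappa = 0 gives a homogeneous hazard and hence uniform stride phases (the
# uncoupled null); large kappa concentrates onsets near phase mu. lambda0
# is set so the mean rate equals the programmed breathing frequency
# (refractory 0.6/f plus mean hazard wait 0.4/f).

.gait_offsets <- list(
  trot   = c(rHL = 0, lFL = 0, lHL = 0.5, rFL = 0.5),
  gallop = c(rHL = 0, lHL = 0.05, rFL = 0.5, lFL = 0.95)
)

#' Simulation scenario
#'
#' Bundles every generative parameter of a synthetic session. Defaults
#' describe a mouse trotting on a treadmill at 40 cm/s: stride 5 Hz, duty
#' factor 0.6, breathing 3.5 Hz at rest rising to 8 Hz while running,
#' inspiratory fraction 0.45 of the breath cycle, uncoupled (`kappa = 0`).
#'
#' @param gait `"trot"`, `"gallop"` or `"rest"`.
#' @param stride_freq stride frequency in Hz.
#' @param duty stance fraction of the stride cycle, in (0, 1).
#' @param belt_speed treadmill belt speed in cm/s.
#' @param f_breath_rest,f_breath_run breathing frequency in Hz at rest and
#'   during the run.
#' @param Ti_frac inspiratory fraction of the breath cycle, in (0, 1).
#' @param cv_cycle multiplicative CV of stride cycle durations.
#' @param kappa von Mises coupling concentration, >= 0 (0 = uncoupled).
#' @param mu preferred stride phase of inspiration onsets, in `[0, 1)`.
#' @param ref_limb limb whose cycle defines the coupling phase.
#' @param snr burst amplitude over baseline-noise SD of the EMG, >= 0.
#' @param fps video frame rate in Hz.
#' @param fs_emg EMG sampling rate in Hz.
#' @param duration total session length in s (rest then run).
#' @param rest_duration initial rest period in s.
#' @param dropout_rate per-frame probability of a tracking failure.
#' @param px_per_cm camera calibration used to emit pixel coordinates.
#' @param noise_px SD of Gaussian pixel noise on tracked points.
#' @param gait_offsets named limb phase offsets overriding the gait preset.
#' @param seed integer RNG seed; the whole session is a pure function of
#'   the scenario including this seed.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(gait = "trot", stride_freq = 5, duty = 0.6,
                         belt_speed = 40, f_breath_rest = 3.5,
                         f_breath_run = 8, Ti_frac = 0.45, cv_cycle = 0.03,
                         kappa = 0, mu = 0.3, ref_limb = "rHL", snr = 8,
                         fps = 200, fs_emg = 1000, duration = 60,
                         rest_duration = 10, dropout_rate = 0.02,
                         px_per_cm = 10, noise_px = 1,
                         gait_offsets = NULL, seed = 1) {
  if (!gait %in% c("trot", "gallop", "rest"))
    stop_parameter("gait must be trot, gallop or rest")
  if (!is_scalar_num(duty) || duty <= 0 || duty >= 1)
    stop_parameter("duty must be in (0, 1)")
  if (!is_scalar_num(Ti_frac) || Ti_frac <= 0 || Ti_frac >= 0.6)
    stop_parameter("Ti_frac must be in (0, 0.6) (refractory bound)")
  if (!is_scalar_num(kappa) || kappa < 0) stop_parameter("kappa must be >= 0")
  if (!is_scalar_num(mu) || mu < 0 || mu >= 1) stop_parameter("mu must be in [0, 1)")
  for (nm in c("stride_freq", "f_breath_rest", "f_breath_run", "fps",
               "fs_emg", "duration", "px_per_cm"))
    if (!is_scalar_num(get(nm)) || get(nm) <= 0)
      stop_parameter("%s must be > 0", nm)
  if (!is_scalar_num(snr) || snr < 0) stop_parameter("snr must be >= 0")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop_parameter("dropout_rate must be in [0, 1]")
  if (rest_duration < 0 || rest_duration >= duration)
    stop_parameter("need 0 <= rest_duration < duration")
  offs <- if (gait == "rest") NULL else .gait_offsets[[gait]]
  if (!is.null(gait_offsets)) offs <- utils::modifyList(as.list(offs), as.list(gait_offsets))
  structure(list(gait = gait, stride_freq = stride_freq, duty = duty,
                 belt_speed = belt_speed, f_breath_rest = f_breath_rest,
                 f_breath_run = f_breath_run, Ti_frac = Ti_frac,
                 cv_cycle = cv_cycle, kappa = kappa, mu = mu,
                 ref_limb = ref_limb, snr = snr, fps = fps, fs_emg = fs_emg,
                 duration = duration, rest_duration = rest_duration,
                 dropout_rate = dropout_rate, px_per_cm = px_per_cm,
                 noise_px = noise_px, offsets = unlist(offs), seed = seed),
            class = "sim_scenario")
}

# master phase function: piecewise linear through jittered cycle boundaries.
# Returns list(phi = function(t), boundaries, limb_event_times(offset))
.master_phase <- function(sc) {
  run_len <- sc$duration - sc$rest_duration
  T_mean <- 1 / sc$stride_freq
  n_cyc <- ceiling(run_len / T_mean * 1.5) + 5L
  Tk <- T_mean * pmax(0.2, 1 + sc$cv_cycle * stats::rnorm(n_cyc))
  bounds <- sc$rest_duration + cumsum(c(0, Tk))
  ks <- seq_along(bounds) - 1L
  phi <- function(t) {
    p <- stats::approx(bounds, ks, xout = t, rule = 2)$y
    p[t <= sc$rest_duration] <- 0
    p
  }
  t_of_phase <- function(ph) stats::approx(ks, bounds, xout = ph)$y
  list(phi = phi, bounds = bounds, t_of_phase = t_of_phase,
       max_phase = ks[length(ks)])
}

#' Simulate limb and head pose tracks for one gait
#'
#' @param sc a [sim_scenario()]. Seeds the RNG from `sc$seed` (restoring
#'   the caller's RNG state) unless called from [simulate_session()].
#' @param .seeded internal: set by [simulate_session()] when the RNG is
#'   already seeded.
#' @return list with `tracks` (named `pose_track` list in pixel units:
#'   rHL, lHL, rFL, lFL, head) and `truth` (footfall and liftoff times per
#'   limb, the master `phi` function, limb offsets, `run_start`).
#' @export
simulate_gait <- function(sc, .seeded = FALSE) {
  stopifnot(inherits(sc, "sim_scenario"))
  run <- function() .simulate_gait_impl(sc)
  if (.seeded) run() else with_seed(sc$seed, run())
}

.simulate_gait_impl <- function(sc) {
  n_fr <- floor(sc$duration * sc$fps) + 1L
  t_fr <- (seq_len(n_fr) - 1L) / sc$fps
  mp <- if (sc$gait == "rest") NULL else .master_phase(sc)

  stride_len <- sc$belt_speed * sc$duty / sc$stride_freq  # cm per stance
  lift <- 0.6                                             # cm swing lift
  x_stand <- c(rHL = 6, lHL = 5.4, rFL = 11, lFL = 10.4)  # cm, camera frame
  y_ground <- c(rHL = 0.5, lHL = 0.5, rFL = 0.5, lFL = 0.5)

  limb_xy <- function(limb) {
    if (sc$gait == "rest") {
      return(list(x = rep(x_stand[[limb]], n_fr),
                  y = rep(y_ground[[limb]], n_fr)))
    }
    u <- mp$phi(t_fr) - sc$offsets[[limb]]
    p <- u %% 1
    pre <- u < 0
    stance <- p < sc$duty
    x <- ifelse(stance, x_stand[[limb]] - stride_len * p / sc$duty,
                x_stand[[limb]] - stride_len +
                  stride_len * (p - sc$duty) / (1 - sc$duty))
    y <- ifelse(stance, y_ground[[limb]],
                y_ground[[limb]] + lift * sin(pi * (p - sc$duty) / (1 - sc$duty)))
    x[pre] <- x_stand[[limb]]; y[pre] <- y_ground[[limb]]
    list(x = x, y = y)
  }

  emit <- function(limb, xy) {
    n <- length(xy$x)
    x_px <- xy$x * sc$px_per_cm + stats::rnorm(n, 0, sc$noise_px)
    y_px <- xy$y * sc$px_per_cm + stats::rnorm(n, 0, sc$noise_px)
    lik <- stats::runif(n, 0.95, 1)
    drop <- stats::runif(n) < sc$dropout_rate
    if (any(drop)) {
      nd <- sum(drop)
      lik[drop] <- stats::runif(nd, 0, 0.4)
      x_px[drop] <- x_px[drop] + sample(c(-1, 1), nd, TRUE) * stats::runif(nd, 30, 80)
      y_px[drop] <- y_px[drop] + sample(c(-1, 1), nd, TRUE) * stats::runif(nd, 30, 80)
    }
    pose_track(limb, x_px, y_px, lik, sc$fps)
  }

  limbs <- c("rHL", "lHL", "rFL", "lFL")
  tracks <- list()
  for (lb in limbs) tracks[[lb]] <- emit(lb, limb_xy(lb))
  head_x <- 20 + stats::rnorm(n_fr, 0, 0.1)  # cm; stable runner
  head_y <- 3 + stats::rnorm(n_fr, 0, 0.05)
  tracks[["head"]] <- emit("head", list(x = head_x, y = head_y))

  truth <- list(run_start = sc$rest_duration,
                footfalls = stats::setNames(vector("list", 4L), limbs),
                liftoffs = stats::setNames(vector("list", 4L), limbs),
                phi = if (is.null(mp)) function(t) rep(0, length(t)) else mp$phi,
                offsets = sc$offsets)
  if (!is.null(mp)) {
    for (lb in limbs) {
      off <- sc$offsets[[lb]]
      ks <- seq(ceiling(off), mp$max_phase - 1L)
      ff <- mp$t_of_phase(ks + off)
      lo <- mp$t_of_phase(ks + off + sc$duty)
      keep <- !is.na(ff) & ff <= sc$duration
      truth$footfalls[[lb]] <- ff[keep]
      truth$liftoffs[[lb]] <- lo[keep & !is.na(lo)]
    }
  }
  list(tracks = tracks, truth = truth)
}

#' Simulate diaphragm EMG with stride-phase-modulated inspiration timing
#'
#' @param sc a [sim_scenario()].
#' @param phase_fun master-phase function of time from [simulate_gait()]'s
#'   truth (`NULL` for a rest-only scenario: uncoupled hazard throughout).
#' @param .seeded internal: RNG already seeded by the caller.
#' @return list with `emg` (`loco_ts` at `fs_emg`), and `truth`:
#'   `insp_onsets`, `insp_offsets` (s), `Ti` (s), and `phase` (the true
#'   stride phase of each onset in the reference limb's cycle; NA outside
#'   the run or at rest gait).
#' @export
simulate_breathing <- function(sc, phase_fun = NULL, .seeded = FALSE) {
  stopifnot(inherits(sc, "sim_scenario"))
  run <- function() .simulate_breathing_impl(sc, phase_fun)
  if (.seeded) run() else with_seed(sc$seed + 500000L, run())
}

.simulate_breathing_impl <- function(sc, phase_fun) {
  ref_off <- if (sc$gait == "rest" || is.null(phase_fun)) 0 else sc$offsets[[sc$ref_limb]]
  coupled <- sc$kappa > 0 && sc$gait != "rest" && !is.null(phase_fun)
  ref_phase <- function(t) {
    if (is.null(phase_fun)) return(rep(0, length(t)))
    (phase_fun(t) - ref_off) %% 1
  }
  f_at <- function(t) {
    if (sc$gait == "rest" || t < sc$rest_duration) sc$f_breath_rest
    else sc$f_breath_run
  }
  I0 <- besselI(sc$kappa, 0)
  lam_at <- function(t) {
    lam0 <- 2.5 * f_at(t)
    if (coupled && t >= sc$rest_duration)
      lam0 * exp(sc$kappa * cos(2 * pi * (ref_phase(t) - sc$mu))) / I0
    else lam0
  }
  lam_max <- 2.5 * max(sc$f_breath_rest, sc$f_breath_run) *
    (if (coupled) exp(sc$kappa) / I0 else 1)

  onsets <- numeric(0)
  t <- stats::rexp(1, lam_max)  # first candidate: no prior refractory
  while (t < sc$duration) {
    # thinning from the global bound
    repeat {
      if (stats::runif(1) < lam_at(t) / lam_max) break
      t <- t + stats::rexp(1, lam_max)
      if (t >= sc$duration) break
    }
    if (t >= sc$duration) break
    onsets <- c(onsets, t)
    t <- t + 0.6 / f_at(t) + stats::rexp(1, lam_max)
  }

  Ti <- vapply(onsets, function(o) sc$Ti_frac / f_at(o), 1.0)
  offsets <- onsets + Ti

  n <- floor(sc$duration * sc$fs_emg)
  sigma0 <- 1
  emg <- stats::rnorm(n, 0, sigma0)
  tt_i <- function(t) pmax(1L, pmin(n, floor(t * sc$fs_emg) + 1L))
  for (j in seq_along(onsets)) {
    i0 <- tt_i(onsets[j]); i1 <- tt_i(offsets[j])
    if (i1 <= i0) next
    m <- i1 - i0 + 1L
    frac <- (seq_len(m) - 0.5) / m
    env <- ifelse(frac <= 0.8, frac / 0.8, (1 - frac) / 0.2)  # ramp then sharp release
    emg[i0:i1] <- emg[i0:i1] + stats::rnorm(m, 0, 1) * sc$snr * sigma0 * env
  }

  phase <- rep(NA_real_, length(onsets))
  if (sc$gait != "rest" && !is.null(phase_fun)) {
    in_run <- onsets >= sc$rest_duration
    phase[in_run] <- ref_phase(onsets[in_run])
  }
  list(emg = time_series(emg, sc$fs_emg),
       truth = list(insp_onsets = onsets, insp_offsets = offsets,
                    Ti = Ti, phase = phase))
}

#' Simulate a complete session (EMG + pose tracks + ground truth)
#'
#' Composes [simulate_gait()] and [simulate_breathing()] on a common clock.
#' Fully determined by `sc$seed`.
#'
#' @param sc a [sim_scenario()].
#' @return list with `emg` (`loco_ts`), `tracks` (named `pose_track` list,
#'   pixel units), `truth` (gait and breathing ground truth merged), and
#'   `cfg` (a matching [session_config()] ready for
#'   [analyze_session()]).
#' @export
simulate_session <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  g <- with_seed(sc$seed, .simulate_gait_impl(sc))
  b <- with_seed(sc$seed + 500000L,
                 .simulate_breathing_impl(sc, g$truth$phi))
  truth <- c(g$truth, b$truth)
  # mark the longest expiratory silence of the rest period as the quiet
  # noise epoch, as an experimenter would when setting the threshold
  noise_epoch <- NULL
  rest_on <- truth$insp_onsets[truth$insp_onsets < sc$rest_duration]
  rest_off <- truth$insp_offsets[truth$insp_onsets < sc$rest_duration]
  if (length(rest_on) >= 2L) {
    gap_start <- rest_off[-length(rest_off)]
    gap_end <- rest_on[-1L]
    j <- which.max(gap_end - gap_start)
    pad <- 0.15 * (gap_end[j] - gap_start[j])
    noise_epoch <- c(gap_start[j] + pad, gap_end[j] - pad)
  }
  cfg <- session_config(
    belt_speed = if (sc$gait == "rest") 0 else sc$belt_speed,
    px_per_cm = sc$px_per_cm,
    condition = sc$gait,
    context = "treadmill",
    fps = sc$fps,
    baseline_epoch = c(0, sc$rest_duration),
    run_epoch = c(sc$rest_duration, sc$duration),
    noise_epoch = noise_epoch,
    resample_fs = sc$fs_emg,
    fs_emg = sc$fs_emg
  )
  list(emg = b$emg, tracks = g$tracks, truth = truth, cfg = cfg, scenario = sc)
}

#' Write a simulated session to disk in the package's external formats
#'
#' EMG as one-column plain text, pose as the 3-header-row CSV dialect,
#' config as YAML, ground-truth event times as CSV tables.
#'
#' @param sim output of [simulate_session()].
#' @param outdir output directory (created if absent).
#' @return invisible named character vector of the files written.
#' @export
write_session <- function(sim, outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop_io("cannot create %s", outdir)
  f_emg <- file.path(outdir, "emg.txt")
  write_timeseries(sim$emg, f_emg)
  f_pose <- file.path(outdir, "pose.csv")
  write_pose_table(sim$tracks, f_pose)
  f_cfg <- file.path(outdir, "config.yaml")
  write_session_config(sim$cfg, f_cfg)
  f_truth <- file.path(outdir, "truth_inspirations.csv")
  tr <- sim$truth
  utils::write.csv(data.frame(onset = tr$insp_onsets, offset = tr$insp_offsets,
                              phase = tr$phase),
                   f_truth, row.names = FALSE)
  f_ff <- file.path(outdir, "truth_footfalls.csv")
  ffdf <- do.call(rbind, lapply(names(tr$footfalls), function(lb) {
    if (!length(tr$footfalls[[lb]])) return(NULL)
    data.frame(limb = lb, footfall = tr$footfalls[[lb]])
  }))
  if (is.null(ffdf)) ffdf <- data.frame(limb = character(0), footfall = numeric(0))
  utils::write.csv(ffdf, f_ff, row.names = FALSE)
  invisible(c(emg = f_emg, pose = f_pose, config = f_cfg,
              inspirations = f_truth, footfalls = f_ff))
}
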