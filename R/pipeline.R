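# End-to-end session analysis and cross-animal aggregation.

.limb_labels <- c("rHL", "lHL", "rFL", "lFL")

.in_epochs <- function(t, epochs) {
  if (nrow(epochs) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (j in seq_len(nrow(epochs)))
    hit <- hit | (t >= epochs$start[j] & t < epochs$end[j])
  hit
}

.with_stage <- function(stage, expr) {
  tryCatch(expr, locoresp_error = function(e) {
    e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
    stop(e)
  })
}

#' Analyse one recording session end-to-end
#'
#' Runs the full chain: EMG integration, burst detection against the
#' baseline epoch, respiratory cycles and amplitude normalisation; pose
#' cleaning, calibration, resampling, stride segmentation per limb, gait
#' classification and stable-epoch selection from the head trace; then,
#' restricted to stable running epochs, inspiration phases, circular
#' statistics and an orientation verdict against each of the four
#' reference limbs, plus windowed respiratory summaries.
#'
#' @param emg raw diaphragm EMG as a `loco_ts`.
#' @param tracks named list of `pose_track` (pixel units) containing at
#'   least the four limbs and the head.
#' @param cfg a [session_config()] with `baseline_epoch` and `run_epoch`
#'   set. Calibration (`px_per_cm`) is applied here; pass 1 if the tracks
#'   are already in cm.
#' @param compute_correlograms also compute EMG-vs-limb cross-correlograms
#'   during the longest stable epoch (slower; default off).
#' @param n_surrogates surrogates per correlogram when enabled.
#' @return an object of class `session_result`; see Details.
#' @details The result is a list: `resp_cycles` (with `amp_pct` column when
#'   a baseline exists), `stride_cycles` (per limb), `epochs`,
#'   `gait`, `phases` and `circ` and `verdicts` (per reference limb),
#'   `summary` (windowed means incl. `amp_pct`), `correlograms` (optional),
#'   `meta` (overlap duration, counts, threshold).
#' @export
analyze_session <- function(emg, tracks, cfg, compute_correlograms = FALSE,
                            n_surrogates = 200) {
  stopifnot(inherits(emg, "loco_ts"), inherits(cfg, "session_config"))
  if (is.null(cfg$baseline_epoch) || is.null(cfg$run_epoch))
    stop_config("cfg must define baseline_epoch and run_epoch")
  missing <- setdiff(c(.limb_labels, "head"), names(tracks))
  if (length(missing))
    stop_config("tracks missing bodypart(s): %s", paste(missing, collapse = ", "))

  # --- temporal overlap of the two recordings
  pose_dur <- length(tracks[[1L]]$x) / tracks[[1L]]$fps
  overlap <- min(ts_duration(emg), pose_dur)
  run_epoch <- c(cfg$run_epoch[1L], min(cfg$run_epoch[2L], overlap))
  if (run_epoch[2L] <= run_epoch[1L])
    stop_config("run_epoch lies outside the recorded overlap (%g s)", overlap)

  # --- respiration
  integrated <- .with_stage("integrate_emg", integrate_emg(emg, cfg$integration_window))
  bcfg <- burst_detect_config(threshold_mode = "robust-baseline",
                              k_mad = cfg$k_mad,
                              hysteresis_frac = cfg$hysteresis_frac,
                              min_Ti = cfg$min_Ti, merge_gap = cfg$merge_gap,
                              integration_window = cfg$integration_window)
  noise_epoch <- if (!is.null(cfg$noise_epoch)) cfg$noise_epoch else cfg$baseline_epoch
  bursts <- .with_stage("detect_bursts",
                        detect_bursts(integrated, bcfg, noise_epoch))
  cycles <- .with_stage("respiratory_cycles", respiratory_cycles(bursts))
  base_cycles <- cycles[cycles$onset >= cfg$baseline_epoch[1L] &
                          cycles$onset < cfg$baseline_epoch[2L], , drop = FALSE]
  if (nrow(base_cycles) > 0L && nrow(cycles) > 0L) {
    cycles$amp_pct <- normalize_amplitude(cycles, base_cycles)
  } else if (nrow(cycles) > 0L) {
    cycles$amp_pct <- NA_real_
  }

  # --- kinematics
  kin <- .with_stage("pose", {
    lapply(tracks[c(.limb_labels, "head")], function(tr) {
      cl <- clean_pose(tr, cfg$likelihood_min, cfg$median_window)
      cl$x <- cl$x / cfg$px_per_cm
      cl$y <- cl$y / cfg$px_per_cm
      resample_track(cl, cfg$resample_fs)
    })
  })
  head_run <- ts_window(kin$head$x, run_epoch[1L], run_epoch[2L])
  v_ref <- NULL
  if (cfg$belt_speed <= 0) {
    hv <- abs(diff(head_run$values)) * head_run$fs
    v_ref <- max(mean(hv), 1e-6)
  }
  strides <- .with_stage("detect_stance_swing", {
    out <- list()
    for (lb in .limb_labels) {
      x_run <- ts_window(kin[[lb]]$x, run_epoch[1L], run_epoch[2L])
      out[[lb]] <- suppressMessages(detect_stance_swing(
        x_run, belt_speed = cfg$belt_speed, v_ref = v_ref,
        vel_window = cfg$vel_window, stance_frac = cfg$stance_frac,
        min_stance = cfg$min_stance, min_swing = cfg$min_swing, limb = lb))
    }
    out
  })

  epochs <- .with_stage("stable_epochs",
                        stable_epochs(head_run, cfg$stable_win,
                                      cfg$stable_max_sd, cfg$stable_max_drift))
  stable <- epochs[epochs$label == "stable", , drop = FALSE]

  gait <- .with_stage("classify_gait", {
    ff <- lapply(strides, attr, "footfalls")
    tryCatch({
      hind <- relative_phase(ff$rHL, ff$lHL)
      fore <- relative_phase(ff$rFL, ff$lFL)
      classify_gait(hind, fore, tol = cfg$gait_tol)
    }, locoresp_parameter_error = function(e)
      list(label = "undetermined", hind_rel_phase = NA_real_,
           fore_rel_phase = NA_real_))
  })

  # --- phase statistics per reference limb, restricted to stable epochs
  onsets_run <- bursts$onset[bursts$onset >= run_epoch[1L] &
                               bursts$onset < run_epoch[2L]]
  onsets_stable <- onsets_run[.in_epochs(onsets_run, stable)]
  phases <- list(); circ <- list(); verdicts <- list()
  for (lb in .limb_labels) {
    st <- strides[[lb]]
    st_stable <- st[.in_epochs(st$footfall_prev, stable) &
                      .in_epochs(st$footfall_next, stable), , drop = FALSE]
    if (nrow(st_stable) == 0L || length(onsets_stable) == 0L) {
      phases[[lb]] <- data.frame(phi = numeric(0), insp_onset = numeric(0),
                                 cycle_index = integer(0),
                                 ref_limb = character(0))
      circ[[lb]] <- NULL
      verdicts[[lb]] <- list(oriented = NA, valid = FALSE, R = NA_real_, n = 0L)
      next
    }
    ph <- inspiration_phases(onsets_stable, st_stable)
    phases[[lb]] <- ph
    if (nrow(ph) > 0L) {
      cs <- circular_stats(ph$phi)
      circ[[lb]] <- cs
      verdicts[[lb]] <- orientation_verdict(cs, R_threshold = cfg$R_threshold,
                                            context = cfg$context)
    } else {
      circ[[lb]] <- NULL
      verdicts[[lb]] <- list(oriented = NA, valid = FALSE, R = NA_real_, n = 0L)
    }
  }

  summary <- .with_stage("select_measurement_windows",
                         select_measurement_windows(cycles, run_epoch,
                                                    cfg$window_s, cfg$n_windows,
                                                    cfg$skip_s))
  if (nrow(base_cycles) > 0L)
    summary$summary[["amp_pct"]] <-
      percent_of_baseline(summary$summary[["amp"]], mean(base_cycles$peak_amp))

  correlograms <- NULL
  if (compute_correlograms && nrow(stable) > 0L) {
    correlograms <- .with_stage("cross_correlogram", {
      j <- which.max(stable$end - stable$start)
      win <- c(stable$start[j], stable$end[j])
      ie <- ts_window(integrated, win[1L], win[2L])
      out <- list()
      for (lb in .limb_labels) {
        xl <- ts_window(kin[[lb]]$x, win[1L], win[2L])
        ml <- min(0.5, (win[2L] - win[1L]) / 8)
        out[[lb]] <- tryCatch(
          cross_correlogram(ie, xl, max_lag = ml,
                            n_surrogates = n_surrogates, seed = 1L),
          locoresp_error = function(e) NULL)
      }
      out
    })
  }

  structure(list(
    resp_cycles = cycles, stride_cycles = strides, epochs = epochs,
    gait = gait, phases = phases, circ = circ, verdicts = verdicts,
    summary = summary, correlograms = correlograms,
    meta = list(overlap = overlap, run_epoch = run_epoch,
                n_bursts = nrow(bursts), n_baseline_cycles = nrow(base_cycles),
                threshold = attr(bursts, "threshold"),
                condition = cfg$condition)
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> condition '%s': %d bursts, gait %s\n",
              x$meta$condition, x$meta$n_bursts, x$gait$label))
  for (lb in names(x$verdicts)) {
    v <- x$verdicts[[lb]]
    cat(sprintf("  ref %-4s R = %s (n = %d) -> %s%s\n", lb,
                ifelse(is.na(v$R), "NA", sprintf("%.3f", v$R)), v$n,
                ifelse(isTRUE(v$oriented), "oriented", "not oriented"),
                ifelse(v$valid, "", " [n below validity minimum]")))
  }
  invisible(x)
}

#' Aggregate session results into a condition summary
#'
#' Each animal contributes its window-averaged respiratory summary; the
#' group mean and sample SD (ddof 1) are computed per parameter. With a
#' single animal the SD is NA and flagged.
#'
#' @param results list of `session_result`, one per animal.
#' @param label condition label.
#' @param animals optional animal identifiers (defaults to `animal1`, ...).
#' @return object of class `condition_summary`: `condition`, `per_animal`
#'   (data frame `condition, parameter, animal, value`), `group` (data
#'   frame `parameter, mean, sd, n`).
#' @export
summarize_condition <- function(results, label, animals = NULL) {
  if (!length(results)) stop_parameter("need at least one session result")
  stopifnot(all(vapply(results, inherits, TRUE, "session_result")))
  if (is.null(animals)) animals <- paste0("animal", seq_along(results))
  params <- c("f", "Ti", "Te", "amp", "amp_pct")
  rows <- list()
  for (i in seq_along(results)) {
    s <- results[[i]]$summary$summary
    for (p in intersect(params, names(s)))
      rows[[length(rows) + 1L]] <- data.frame(condition = label, parameter = p,
                                              animal = animals[i],
                                              value = unname(s[[p]]))
  }
  per_animal <- do.call(rbind, rows)
  group <- do.call(rbind, lapply(split(per_animal, per_animal$parameter),
                                 function(d) data.frame(
                                   parameter = d$parameter[1L],
                                   mean = mean(d$value),
                                   sd = if (nrow(d) > 1L) stats::sd(d$value) else NA_real_,
                                   n = nrow(d))))
  rownames(group) <- NULL
  structure(list(condition = label, per_animal = per_animal, group = group),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> '%s' (n = %d animals)\n", x$condition,
              length(unique(x$per_animal$animal))))
  print(x$group)
  invisible(x)
}

#' Significance mark for a p-value
#'
#' Standard bands: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, `ns` otherwise.
#'
#' @param p p-value.
#' @return character mark.
#' @export
significance_mark <- function(p) {
  if (!is_scalar_num(p) || p < 0 || p > 1) stop_parameter("p must be in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare one respiratory parameter between two conditions
#'
#' Mann-Whitney U test on the per-animal values, with the standard
#' significance mark attached.
#'
#' @param a,b `condition_summary` objects.
#' @param parameter one of `"f"`, `"Ti"`, `"Te"`, `"amp"`, `"amp_pct"`.
#' @return list with `U`, `p`, `mark`, `parameter`, `conditions`.
#' @export
compare_conditions <- function(a, b, parameter = "f") {
  stopifnot(inherits(a, "condition_summary"), inherits(b, "condition_summary"))
  va <- a$per_animal$value[a$per_animal$parameter == parameter]
  vb <- b$per_animal$value[b$per_animal$parameter == parameter]
  if (!length(va) || !length(vb))
    stop_parameter("parameter '%s' absent from one condition", parameter)
  mw <- mann_whitney_u(va, vb)
  list(U = mw$U, p = mw$p_two_sided, mark = significance_mark(mw$p_two_sided),
       parameter = parameter, conditions = c(a$condition, b$condition))
}
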