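test_that("integrate_emg matches closed forms", {
  # all-zero input stays zero
  z <- integrate_emg(time_series(rep(0, 500), 1000), window = 0.015)
  expect_equal(z$values, rep(0, 500))

  # sine of amplitude A over an integer number of periods: interior A/sqrt(2)
  # (window 125 samples = 5 periods of a 40 Hz sine at 1 kHz)
  A <- 2.5
  x <- time_series(A * sin(2 * pi * 40 * (0:1999) / 1000), 1000)
  env <- integrate_emg(x, window = 0.125)
  interior <- env$values[200:1800]
  expect_lt(max(abs(interior - A / sqrt(2))), 1e-9)

  # unit impulse in an N-sample window: interior peak 1/sqrt(N)
  v <- rep(0, 301); v[151] <- 1
  env <- integrate_emg(time_series(v, 1000), window = 0.015)  # N = 15
  expect_equal(max(env$values), 1 / sqrt(15))

  expect_error(integrate_emg(time_series(1:10, 100), window = 0.005),
               class = "locoresp_parameter_error")
})

test_that("detect_bursts handles square waves, silence and merging", {
  fs <- 1000
  # 50 ms at 1.0, 150 ms at 0.0, repeated 5x
  v <- rep(c(rep(1, 50), rep(0, 150)), 5)
  cfg <- burst_detect_config(threshold_mode = "absolute", threshold = 0.5,
                             merge_gap = 0, min_Ti = 0)
  b <- detect_bursts(time_series(v, fs), cfg)
  expect_identical(nrow(b), 5L)
  expect_true(all(abs((b$offset - b$onset) - 0.05) <= 1 / fs))
  expect_equal(b$peak_amp, rep(1, 5))

  # flat sub-threshold signal: empty, not an error
  b0 <- detect_bursts(time_series(rep(0.1, 1000), fs), cfg)
  expect_identical(nrow(b0), 0L)

  # two 40 ms plateaus, 10 ms sub-threshold gap, merge_gap 30 ms -> one
  # 90 ms burst (hand trace of the merge rule)
  v2 <- c(rep(0, 100), rep(1, 40), rep(0, 10), rep(1, 40), rep(0, 100))
  cfgm <- burst_detect_config(threshold_mode = "absolute", threshold = 0.5,
                              merge_gap = 0.03, min_Ti = 0)
  bm <- detect_bursts(time_series(v2, fs), cfgm)
  expect_identical(nrow(bm), 1L)
  expect_equal(bm$offset - bm$onset, 0.09)

  # with merge_gap 0 the two plateaus stay separate
  b2 <- detect_bursts(time_series(v2, fs), cfg)
  expect_identical(nrow(b2), 2L)

  # min_Ti discards short bursts
  cfgt <- burst_detect_config(threshold_mode = "absolute", threshold = 0.5,
                              merge_gap = 0, min_Ti = 0.06)
  expect_identical(nrow(detect_bursts(time_series(v2, fs), cfgt)), 0L)
})

test_that("detect_bursts equals the brute-force scan without hysteresis", {
  cfg <- burst_detect_config(threshold_mode = "absolute", threshold = 1.2,
                             hysteresis_frac = 1, merge_gap = 0, min_Ti = 0)
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(200:10000, 1)
    # smooth positive trace with occasional excursions
    v <- abs(as.numeric(stats::filter(rnorm(n, 0.4, 0.8), rep(0.2, 5),
                                      circular = TRUE)))
    got <- detect_bursts(time_series(v, 1000), cfg)
    want <- oracle_burst_scan(v, 1.2, 1000)
    expect_equal(got$onset, want$onset)
    expect_equal(got$offset, want$offset)
    expect_equal(got$peak_amp, want$peak_amp)
  }
})

test_that("raising the absolute threshold shrinks detections monotonically", {
  # Count monotonicity holds when individual bursts are unimodal (each
  # burst's supra-threshold set is a single interval); an arbitrary trace
  # can split one run into two as the threshold rises through an
  # intra-burst dip, so the property is asserted on unimodal-burst traces
  # and, for arbitrary traces, on the total supra-threshold duration.
  set.seed(12)
  for (rep in 1:10) {
    tt <- (0:2999) / 1000
    v <- rep(0, 3000)
    centers <- 0.2 + cumsum(runif(sample(3:7, 1), 0.25, 0.45))
    for (cc in centers)
      v <- v + runif(1, 0.5, 2) * exp(-(tt - cc)^2 / (2 * 0.02^2))
    counts <- vapply(seq(0.2, 1.6, by = 0.2), function(thr) {
      cfg <- burst_detect_config(threshold_mode = "absolute", threshold = thr,
                                 hysteresis_frac = 1, merge_gap = 0, min_Ti = 0)
      nrow(detect_bursts(time_series(v, 1000), cfg))
    }, 1L)
    expect_true(all(diff(counts) <= 0))
  }
  # arbitrary rough traces: total burst duration is monotone
  for (rep in 1:5) {
    v <- abs(as.numeric(stats::filter(rnorm(3000, 0.3, 1), rep(1 / 15, 15),
                                      circular = TRUE)))
    durs <- vapply(seq(0.2, 1.2, by = 0.1), function(thr) {
      cfg <- burst_detect_config(threshold_mode = "absolute", threshold = thr,
                                 hysteresis_frac = 1, merge_gap = 0, min_Ti = 0)
      b <- detect_bursts(time_series(v, 1000), cfg)
      sum(b$offset - b$onset)
    }, 1.0)
    expect_true(all(diff(durs) <= 1e-12))
  }
})

test_that("robust-baseline thresholding needs and uses a baseline epoch", {
  v <- c(rep(0.1, 500), rep(5, 50), rep(0.1, 450))
  x <- time_series(v, 1000)
  expect_error(detect_bursts(x, burst_detect_config()),
               class = "locoresp_parameter_error")
  expect_error(detect_bursts(x, burst_detect_config(),
                             baseline_epoch = c(10, 11)),
               class = "locoresp_parameter_error")
  b <- detect_bursts(x, burst_detect_config(), baseline_epoch = c(0, 0.4))
  expect_identical(nrow(b), 1L)
})

test_that("respiratory_cycles computes Ti, Te, f_inst", {
  # onsets 0, 0.2, 0.4 with 50 ms bursts: Te = 150 ms, f = 5 Hz
  b <- data.frame(onset = c(0, 0.2, 0.4), offset = c(0.05, 0.25, 0.45),
                  peak_amp = c(1, 2, 3))
  cyc <- respiratory_cycles(b)
  expect_identical(nrow(cyc), 2L)
  expect_equal(cyc$Ti, c(0.05, 0.05))
  expect_equal(cyc$Te, c(0.15, 0.15))
  expect_equal(cyc$f_inst, c(5, 5))

  # Ti 60 ms, next onset at 125 ms: Te 65 ms, f 8 Hz
  b2 <- data.frame(onset = c(0, 0.125), offset = c(0.06, 0.185),
                   peak_amp = c(1, 1))
  cyc2 <- respiratory_cycles(b2)
  expect_equal(cyc2$Te, 0.065)
  expect_equal(cyc2$f_inst, 8)

  expect_identical(nrow(suppressMessages(
    respiratory_cycles(b[1, ]))), 0L)
})

test_that("cycle onsets telescope: onset_{n+1} - onset_n = Ti + Te", {
  sim <- quick_session(seed = 21, duration = 30, rest = 8)
  int <- integrate_emg(sim$emg, 0.015)
  b <- detect_bursts(int, burst_detect_config(),
                     baseline_epoch = sim$cfg$noise_epoch)
  cyc <- respiratory_cycles(b)
  expect_gt(nrow(cyc), 50)
  expect_lt(max(abs(diff(b$onset) - (cyc$Ti + cyc$Te))), 1 / sim$emg$fs)
})

test_that("normalize_amplitude is percent of baseline mean", {
  base <- data.frame(peak_amp = c(2, 2))
  run <- data.frame(peak_amp = 3)
  expect_equal(normalize_amplitude(run, base), 150)
  expect_equal(normalize_amplitude(data.frame(peak_amp = 2), base), 100)
  expect_equal(normalize_amplitude(data.frame(peak_amp = c(1, 2, 4)),
                                   data.frame(peak_amp = c(1, 3))),
               c(50, 100, 200))
  expect_error(normalize_amplitude(run, base[0, , drop = FALSE]),
               class = "locoresp_parameter_error")
})

test_that("measurement windows respect skip and shortness rules", {
  mk_cycles <- function(f, t0, t1) {
    onset <- seq(t0, t1, by = 1 / f)
    data.frame(onset = onset, Ti = 0.4 / f, Te = 0.6 / f, f_inst = f,
               peak_amp = 1)
  }
  # 120 s epoch at constant 8 Hz: averaged 8 Hz, windows start >= 20 s
  w <- select_measurement_windows(mk_cycles(8, 0, 120), c(0, 120))
  expect_false(w$warning)
  expect_true(all(w$windows$start >= 20))
  expect_equal(unname(w$summary["f"]), 8)
  expect_true(all(w$windows$n_cycles >= 40))

  # 24 s epoch, window 6, skip 20: single 4-s window + warning flag
  w2 <- select_measurement_windows(mk_cycles(8, 0, 24), c(0, 24))
  expect_true(w2$warning)
  expect_identical(nrow(w2$windows), 1L)
  expect_equal(w2$windows$start, 20)
  expect_equal(w2$windows$end, 24)

  # 4 Hz before 20 s, 8 Hz after: the skip rule reports 8 Hz
  cyc <- rbind(mk_cycles(4, 0, 19.9), mk_cycles(8, 20, 60))
  w3 <- select_measurement_windows(cyc, c(0, 60))
  expect_equal(unname(w3$summary["f"]), 8)
})
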