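test_that("inspiration_phases assigns phases with the half-open convention", {
  strides <- data.frame(limb = "rHL", footfall_prev = c(0, 0.5),
                        liftoff = c(0.3, 0.8), footfall_next = c(0.5, 1.0))
  ph <- inspiration_phases(0.125, strides)
  expect_equal(ph$phi, 0.25)
  expect_identical(ph$cycle_index, 1L)

  # an onset exactly at a footfall opens the cycle that starts there
  ph2 <- inspiration_phases(0.5, strides)
  expect_equal(ph2$phi, 0)
  expect_identical(ph2$cycle_index, 2L)

  # footfalls {0, 0.4, 0.8}: onsets {0.1, 0.5, 0.9} -> {0.25, 0.25}, one
  # excluded past the last footfall
  s3 <- data.frame(limb = "rHL", footfall_prev = c(0, 0.4),
                   liftoff = c(0.2, 0.6), footfall_next = c(0.4, 0.8))
  ph3 <- inspiration_phases(c(0.1, 0.5, 0.9), s3)
  expect_equal(ph3$phi, c(0.25, 0.25))
  expect_identical(attr(ph3, "n_excluded"), 1L)

  # onsets in inter-cycle gaps are excluded too
  s4 <- data.frame(limb = "rHL", footfall_prev = c(0, 1),
                   liftoff = c(0.2, 1.2), footfall_next = c(0.4, 1.4))
  ph4 <- inspiration_phases(c(0.2, 0.6, 1.2), s4)
  expect_equal(nrow(ph4), 2L)
  expect_identical(attr(ph4, "n_excluded"), 1L)

  expect_error(inspiration_phases(0.1, s3[0, ]),
               class = "locoresp_parameter_error")
})

test_that("circular_stats matches hand values and flags degeneracy", {
  cs <- circular_stats(rep(0.25, 7))
  expect_equal(cs$mean_phase, 0.25)
  expect_equal(cs$R, 1)

  # perfectly balanced phases: R = 0, mean undefined
  cs0 <- circular_stats(c(0, 0.25, 0.5, 0.75))
  expect_lt(cs0$R, 1e-9)
  expect_true(is.na(cs0$mean_phase))

  # frozen from the complex-sum oracle: phases {0.1, 0.2, 0.3}
  cs3 <- circular_stats(c(0.1, 0.2, 0.3))
  expect_equal(cs3$mean_phase, 0.2, tolerance = 1e-12)
  expect_equal(cs3$R, 0.87267799624997, tolerance = 1e-9)

  expect_error(circular_stats(numeric(0)), class = "locoresp_parameter_error")
})

test_that("circular_stats agrees with the complex-sum oracle", {
  set.seed(61)
  for (rep in 1:1000) {
    ph <- runif(sample(1:80, 1))
    got <- circular_stats(ph)
    want <- oracle_circ(ph)
    expect_equal(got$R, want$R, tolerance = 1e-12)
    if (got$R > 1e-9)
      expect_equal(got$mean_phase, want$mean_phase, tolerance = 1e-12)
  }
})

test_that("R is rotation-invariant and the mean phase tracks the rotation", {
  set.seed(62)
  for (rep in 1:50) {
    ph <- runif(30)
    rot <- runif(1)
    a <- circular_stats(ph)
    b <- circular_stats((ph + rot) %% 1)
    expect_equal(a$R, b$R, tolerance = 1e-12)
    d <- (b$mean_phase - a$mean_phase - rot) %% 1
    expect_lt(min(d, 1 - d), 1e-9)
  }
})

test_that("orientation_verdict applies the fixed R and n rules", {
  mk <- function(R, n) structure(list(mean_phase = 0.2, R = R, n = n),
                                 class = "circ_stats")
  v <- orientation_verdict(mk(0.87, 40), context = "treadmill")
  expect_true(v$oriented); expect_true(v$valid)
  v2 <- orientation_verdict(mk(0.10, 40), context = "treadmill")
  expect_false(v2$oriented); expect_true(v2$valid)
  # R above threshold but too few breaths: oriented yet invalid
  v3 <- orientation_verdict(mk(0.5, 10), context = "treadmill")
  expect_true(v3$oriented); expect_false(v3$valid)
  # the air-puff context needs only 20 breaths
  expect_true(orientation_verdict(mk(0.5, 25), context = "airpuff")$valid)
  expect_false(orientation_verdict(mk(0.5, 25), context = "treadmill")$valid)
})

test_that("rayleigh_p evaluates exp(-n R^2) and is monotone in n", {
  mk <- function(R, n) structure(list(mean_phase = 0, R = R, n = n),
                                 class = "circ_stats")
  expect_equal(rayleigh_p(mk(0, 13)), 1)
  expect_equal(rayleigh_p(mk(0.3, 40)), exp(-3.6))
  ps <- vapply(c(10, 20, 40, 80), function(n) rayleigh_p(mk(0.3, n)), 1.0)
  expect_true(all(diff(ps) < 0))
})

test_that("phase_histogram bins on the half-open grid", {
  h <- phase_histogram((0:39) / 40, n_bins = 10)
  expect_equal(as.numeric(h), rep(4, 10))
  h2 <- phase_histogram(rep(0.05, 17), n_bins = 10)
  expect_equal(as.numeric(h2), c(17, rep(0, 9)))
  expect_equal(which(phase_histogram(0.999, 10) == 1), 10L)
  # counts always sum to n; pairwise merging preserves totals
  set.seed(63)
  for (rep in 1:20) {
    ph <- runif(sample(1:200, 1))
    h <- phase_histogram(ph, 10)
    expect_identical(sum(h), length(ph))
    merged <- h[seq(1, 9, by = 2)] + h[seq(2, 10, by = 2)]
    expect_identical(sum(merged), length(ph))
    expect_equal(as.numeric(merged), as.numeric(phase_histogram(ph, 5)))
  }
  expect_error(phase_histogram(numeric(0)), class = "locoresp_parameter_error")
  expect_error(phase_histogram(0.5, 1), class = "locoresp_parameter_error")
})

test_that("cross_correlogram normalizes, peaks at delays, and validates", {
  # identical periodic signals: r(0) = 1 (shift surrogates cannot flag a
  # strictly periodic common signal, so no flatness assertion here)
  tt <- seq(0, 9.995, by = 0.005)
  s <- time_series(sin(2 * pi * 3.3 * tt), 200)
  cg <- cross_correlogram(s, s, max_lag = 0.25, n_surrogates = 200, seed = 1)
  expect_equal(cg$r[cg$lags == 0], 1, tolerance = 1e-9)
  expect_length(cg$band_lo, length(cg$lags))

  # identical noise: emphatically not flat
  set.seed(64)
  a <- time_series(rnorm(2000), 200)
  cga <- cross_correlogram(a, a, max_lag = 0.25, n_surrogates = 200, seed = 2)
  expect_false(cga$flat)

  # delayed copy peaks at the programmed lag within one sample
  x <- rnorm(3000)
  b <- time_series(c(rep(0, 20), x[1:2980]), 200)
  cgd <- cross_correlogram(time_series(x, 200), b, max_lag = 0.3,
                           n_surrogates = 200, seed = 3)
  expect_equal(cgd$lags[which.max(cgd$r)], 0.1, tolerance = 1 / 200 + 1e-9)
  expect_false(cgd$flat)

  expect_error(cross_correlogram(a, time_series(rnorm(100), 100), 0.1),
               class = "locoresp_parameter_error")
  expect_error(cross_correlogram(a, time_series(rep(1, 2000), 200), 0.25),
               class = "locoresp_validation_error")
  expect_error(cross_correlogram(a, time_series(rnorm(2000), 200), 3),
               class = "locoresp_parameter_error")
})

test_that("mann_whitney_u matches enumeration and its symmetries", {
  got <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p_two_sided, 0.1)
  expect_identical(got$method, "exact")

  # identical samples (ties force the normal branch): p = 1
  same <- mann_whitney_u(c(3, 1, 2), c(1, 2, 3))
  expect_identical(same$method, "normal")
  expect_equal(same$p_two_sided, 1)

  # swapping samples preserves p and reflects U
  set.seed(65)
  for (rep in 1:20) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
    f <- mann_whitney_u(a, b); g <- mann_whitney_u(b, a)
    expect_equal(f$p_two_sided, g$p_two_sided)
    expect_equal(g$U, length(a) * length(b) - f$U)
  }
  expect_error(mann_whitney_u(numeric(0), 1),
               class = "locoresp_parameter_error")
})

test_that("exact Mann-Whitney branch equals brute force for n <= 6", {
  set.seed(66)
  for (rep in 1:30) {
    a <- round(rnorm(sample(2:6, 1)), 6)
    b <- round(rnorm(sample(2:6, 1)), 6)
    if (anyDuplicated(c(a, b))) next
    got <- mann_whitney_u(a, b)
    want <- oracle_mw(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$U, want$U)
    expect_equal(got$p_two_sided, want$p)
  }
})

test_that("percent_of_baseline uses the ratio convention", {
  expect_equal(percent_of_baseline(4, 4), 100)
  expect_equal(percent_of_baseline(9, 4), 225)
  expect_equal(percent_of_baseline(8, 3.5), 228.5714286, tolerance = 1e-6)
  expect_error(percent_of_baseline(1, 0), class = "locoresp_parameter_error")
})

test_that("P(R >= 0.3) under uniform phases at n = 40 is below 0.05", {
  set.seed(67)
  hits <- mean(replicate(2000, circular_stats(runif(40))$R >= 0.3))
  expect_lte(hits, 0.05)
  # analytic cross-check: first-order Rayleigh tail exp(-40 * 0.09) ~ 0.027
  expect_equal(exp(-40 * 0.3^2), 0.02732372, tolerance = 1e-6)
})
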