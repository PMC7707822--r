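# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# circular statistics via the complex sum |mean(e^{i theta})|
oracle_circ <- function(phases) {
  z <- mean(exp(2i * pi * phases))
  list(mean_phase = (Arg(z) / (2 * pi)) %% 1, R = Mod(z))
}

# exact two-sided Mann-Whitney p by full enumeration of labelings
oracle_mw <- function(a, b) {
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  comb <- utils::combn(na + nb, na)
  Us <- colSums(matrix(rk[comb], nrow = na)) - na * (na + 1) / 2
  m <- na * nb / 2
  list(U = U, p = mean(abs(Us - m) >= abs(U - m) - 1e-12))
}

# brute-force super-threshold run scan (no hysteresis, no merging)
oracle_burst_scan <- function(v, thr, fs, t0 = 0) {
  above <- v >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(onset = t0 + (starts[keep] - 1) / fs,
             offset = t0 + ends[keep] / fs,
             peak_amp = vapply(keep, function(k) max(v[starts[k]:ends[k]]), 1.0))
}

# deterministic renewal-kernel oracle for the stationary event-phase
# distribution of the von Mises-modulated hazard with absolute refractory:
# an event at reference phase a is followed by a dead time of
# 0.6/f_breath (in s, i.e. 0.6*nu/f cycles at stride rate nu), then the
# next event is the first passage of an inhomogeneous hazard
# lambda(phi) = lambda0 exp(kappa cos(2 pi (phi - mu)))/I0(kappa) along
# the phase sweep. Pure quadrature + power iteration; no RNG.
oracle_vm_event_phase <- function(stride_freq, f_breath, kappa, mu,
                                  G = 360, du = 5e-4, U = 8) {
  nu <- stride_freq
  lam0 <- 2.5 * f_breath
  lam_phase <- function(phi)
    lam0 * exp(kappa * cos(2 * pi * (phi - mu))) / besselI(kappa, 0) / nu
  refr <- 0.6 / f_breath * nu               # cycles
  grid <- (seq_len(G) - 0.5) / G
  u <- seq(0, U, by = du)
  K <- matrix(0, G, G)                      # K[j, i] = P(next in bin j | prev bin i)
  for (i in seq_len(G)) {
    s <- grid[i] + refr
    lam_u <- lam_phase((s + u) %% 1)
    H <- cumsum(lam_u) * du
    dens <- lam_u * exp(-(H - lam_u * du))  # first-passage density over u
    w <- dens * du
    bins <- floor(((s + u) %% 1) * G) + 1L
    bins[bins > G] <- G
    agg <- rowsum(w, bins)
    kk <- numeric(G)
    kk[as.integer(rownames(agg))] <- agg[, 1L]
    K[, i] <- kk / sum(kk)
  }
  p <- rep(1 / G, G)
  for (it in 1:200) p <- as.numeric(K %*% p)
  z <- sum(p * exp(2i * pi * grid))
  list(mean_phase = (Arg(z) / (2 * pi)) %% 1, R = Mod(z))
}

# small, fast default synthetic session for pipeline tests
quick_session <- function(seed, kappa = 0, duration = 40, rest = 10, ...) {
  simulate_session(sim_scenario(seed = seed, kappa = kappa,
                                duration = duration, rest_duration = rest, ...))
}
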