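# Circular statistics of inspiration timing within the stride cycle.
# Each inspiratory burst onset falling inside a stride cycle gets a phase
# phi in [0,1): 0 at the preceding footfall, 1 at the next. The mean
# resultant length R of the phases measures their concentration; mean
# phases with R below a fixed threshold (0.3) are treated as not
# significantly oriented.

#' Assign inspiration onsets a phase within stride cycles
#'
#' For an onset `t` inside the cycle `[FF_prev, FF_next)`:
#' `phi = (t - FF_prev) / (FF_next - FF_prev)`. Onsets before the first
#' footfall, after the last, or in gaps between cycles are excluded; the
#' excluded count is attached as attribute `"n_excluded"`. An onset exactly
#' at a footfall belongs to the cycle that starts there (half-open
#' convention).
#'
#' @param insp_onsets burst onset times in s.
#' @param strides stride-cycle data frame (ordered, non-overlapping;
#'   columns `limb`, `footfall_prev`, `footfall_next`).
#' @return data frame with columns `phi`, `insp_onset`, `cycle_index`,
#'   `ref_limb`.
#' @export
inspiration_phases <- function(insp_onsets, strides) {
  if (!is.data.frame(strides) || nrow(strides) == 0L)
    stop_parameter("strides must be a non-empty stride-cycle table")
  if (is.unsorted(strides$footfall_prev, strictly = TRUE))
    stop_validation("stride cycles must be strictly ordered")
  k <- findInterval(insp_onsets, strides$footfall_prev)
  inside <- k >= 1L & insp_onsets < strides$footfall_next[pmax(k, 1L)]
  phi <- (insp_onsets[inside] - strides$footfall_prev[k[inside]]) /
    (strides$footfall_next[k[inside]] - strides$footfall_prev[k[inside]])
  structure(
    data.frame(phi = phi, insp_onset = insp_onsets[inside],
               cycle_index = k[inside],
               ref_limb = if (nrow(strides)) strides$limb[1L] else NA_character_),
    n_excluded = sum(!inside)
  )
}

#' Circular mean phase and concentration
#'
#' Phases in cycle units are mapped to angles `theta = 2*pi*phi`; with
#' `C = mean(cos theta)` and `S = mean(sin theta)`, the mean resultant
#' length is `R = sqrt(C^2 + S^2)` and the mean phase
#' `atan2(S, C) / (2*pi) mod 1`. `R` is 1 iff all phases coincide and 0
#' for perfectly balanced phases, in which case the mean phase is
#' undefined and reported as NA.
#'
#' @param phases numeric vector of phases in `[0, 1)`, length >= 1.
#' @return list of class `circ_stats` with `mean_phase`, `R`, `n`.
#' @export
circular_stats <- function(phases) {
  if (length(phases) < 1L) stop_parameter("need at least one phase")
  if (anyNA(phases) || any(!is.finite(phases)))
    stop_validation("non-finite phases")
  th <- 2 * pi * phases
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- min(1, sqrt(C^2 + S^2))
  mp <- if (R < 1e-9) NA_real_ else (atan2(S, C) / (2 * pi)) %% 1
  structure(list(mean_phase = mp, R = R, n = length(phases)),
            class = "circ_stats")
}

#' @export
print.circ_stats <- function(x, ...) {
  cat(sprintf("<circ_stats> n = %d, mean phase = %s, R = %.4f\n",
              x$n, if (is.na(x$mean_phase)) "undefined" else sprintf("%.4f", x$mean_phase),
              x$R))
  invisible(x)
}

#' Orientation verdict for a mean phase
#'
#' The fixed-criterion rule: a mean phase is considered significantly
#' oriented iff the concentration `R` is at least `R_threshold` (0.3).
#' Validity is a separate flag requiring a minimum number of breaths:
#' 35 on the treadmill, 20 in the air-puff context.
#'
#' @param stats a `circ_stats`.
#' @param R_threshold concentration threshold.
#' @param context `"treadmill"` or `"airpuff"`.
#' @param min_n named minimum sample sizes per context.
#' @return list with `oriented`, `valid`, `R`, `n`.
#' @export
orientation_verdict <- function(stats, R_threshold = 0.3,
                                context = c("treadmill", "airpuff"),
                                min_n = c(treadmill = 35, airpuff = 20)) {
  stopifnot(inherits(stats, "circ_stats"))
  context <- match.arg(context)
  list(oriented = stats$R >= R_threshold,
       valid = stats$n >= min_n[[context]],
       R = stats$R, n = stats$n)
}

#' First-order Rayleigh p-value
#'
#' `p = exp(-n * R^2)`, clipped to (0, 1]. A significance companion to the
#' fixed concentration criterion; it never replaces the verdict.
#'
#' @param stats a `circ_stats`.
#' @return scalar p-value.
#' @export
rayleigh_p <- function(stats) {
  stopifnot(inherits(stats, "circ_stats"))
  min(1, max(.Machine$double.xmin, exp(-stats$n * stats$R^2)))
}

#' Phase distribution histogram
#'
#' Equal-width half-open bins `[k/n_bins, (k+1)/n_bins)` over `[0, 1)`.
#'
#' @param phases numeric phases in `[0, 1)`, length >= 1.
#' @param n_bins number of bins, >= 2.
#' @return integer counts per bin (sums to `length(phases)`); bin left
#'   edges attached as attribute `"breaks"`.
#' @export
phase_histogram <- function(phases, n_bins = 10) {
  if (length(phases) < 1L) stop_parameter("need at least one phase")
  if (n_bins < 2L) stop_parameter("n_bins must be >= 2")
  if (any(phases < 0 | phases >= 1)) stop_validation("phases must lie in [0, 1)")
  bin <- pmin(floor(phases * n_bins) + 1L, n_bins)
  structure(tabulate(bin, nbins = n_bins),
            breaks = (seq_len(n_bins) - 1L) / n_bins)
}

#' Surrogate-calibrated cross-correlogram
#'
#' Both signals are z-scored; the correlogram is the normalized cross
#' correlation at every integer-sample lag in `[-max_lag, max_lag]`. The
#' null envelope is built from `n_surrogates` circular time shifts of `b`
#' (uniform random shift of at least `max_lag`), which preserve each
#' signal's autocorrelation while destroying their alignment. The
#' correlogram is flagged `flat` iff it stays inside the envelope at every
#' lag.
#'
#' The envelope is a simultaneous band: per lag it is
#' `median +/- tau * sd` over the surrogate correlograms, with the
#' multiplier `tau = qnorm(1 - alpha/(4m))` (m = number of lags) chosen so
#' the family-wise probability of any lag escaping under the null is about
#' `alpha/2` (Bonferroni split of the band's two-sided `alpha/2`
#' allocation across lags). A naive per-lag `alpha/2` quantile band would
#' be exceeded somewhere by almost every null realisation once a hundred
#' lags are scanned; for smooth signals neighbouring lags are correlated
#' and the band is conservative, which is the right failure mode for a
#' verdict named "flat".
#'
#' Known limitation: circular shifts preserve strict periodicity, so a
#' noiseless periodic signal correlated with itself is indistinguishable
#' from its own surrogates and is reported flat; any aperiodic component
#' (noise, jitter) restores detection.
#'
#' @param a,b `loco_ts` at the same sampling rate; the overlapping support
#'   must be at least `4 * max_lag`.
#' @param max_lag maximum lag in s.
#' @param n_surrogates number of circular-shift surrogates.
#' @param alpha two-sided envelope level.
#' @param seed RNG seed for the surrogate shifts (NULL = current stream).
#' @return list of class `correlogram`: `lags` (s), `r`, `band_lo`,
#'   `band_hi`, `flat`.
#' @export
cross_correlogram <- function(a, b, max_lag, n_surrogates = 1000,
                              alpha = 0.05, seed = NULL) {
  stopifnot(inherits(a, "loco_ts"), inherits(b, "loco_ts"))
  if (abs(a$fs - b$fs) > 1e-9) stop_parameter("signals must share a sampling rate")
  fs <- a$fs
  n <- min(length(a$values), length(b$values))
  if (n / fs < 4 * max_lag)
    stop_parameter("overlapping support (%g s) shorter than 4 * max_lag", n / fs)
  za <- a$values[seq_len(n)]; zb <- b$values[seq_len(n)]
  if (stats::sd(za) == 0 || stats::sd(zb) == 0)
    stop_validation("zero-variance input")
  za <- (za - mean(za)) / (stats::sd(za) * sqrt((n - 1) / n))
  zb <- (zb - mean(zb)) / (stats::sd(zb) * sqrt((n - 1) / n))
  L <- round(max_lag * fs)
  lags_i <- -L:L
  # r(k) = sum_t za[t] bb[t+k] / (n - |k|), via zero-padded FFT
  N <- stats::nextn(n + L + 1L)
  fa <- stats::fft(c(za, rep(0, N - n)))
  xc <- function(bb) {
    fb <- stats::fft(c(bb, rep(0, N - n)))
    cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / N
    idx <- ifelse(lags_i >= 0, lags_i + 1L, N + lags_i + 1L)
    cc[idx] / (n - abs(lags_i))
  }
  r <- xc(zb)
  shifts <- with_seed(seed, sample(seq.int(L, n - L), n_surrogates, replace = TRUE))
  sur <- matrix(0, n_surrogates, length(lags_i))
  for (s in seq_len(n_surrogates)) {
    sh <- shifts[s]
    sur[s, ] <- xc(c(zb[(sh + 1L):n], zb[seq_len(sh)]))
  }
  med <- apply(sur, 2L, stats::median)
  sdv <- apply(sur, 2L, stats::sd)
  sdv[sdv < .Machine$double.eps] <- .Machine$double.eps
  m <- length(lags_i)
  tau <- stats::qnorm(1 - alpha / (4 * m))
  band_lo <- med - tau * sdv
  band_hi <- med + tau * sdv
  structure(list(lags = lags_i / fs, r = r, band_lo = band_lo,
                 band_hi = band_hi,
                 flat = all(r >= band_lo & r <= band_hi)),
            class = "correlogram")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. With no ties and the smaller sample of size at
#' most 8, the p-value is exact by full enumeration of all assignments of
#' the pooled ranks; otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b numeric samples, both non-empty.
#' @return list with `U` (for sample `a`), `p_two_sided`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop_parameter("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && min(na, nb) <= 8L) {
    comb <- utils::combn(na + nb, na)
    # ranks are 1..N with no ties; U for each labeling of which pooled
    # order statistics are called "a"
    Us <- colSums(matrix(rk[comb], nrow = na)) - na * (na + 1) / 2
    m <- na * nb / 2
    p <- mean(abs(Us - m) >= abs(U - m) - 1e-12)
    return(list(U = U, p_two_sided = p, method = "exact"))
  }
  # normal approximation with tie correction
  N <- na + nb
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  m <- na * nb / 2
  if (sigma2 <= 0) return(list(U = U, p_two_sided = 1, method = "normal"))
  z <- (abs(U - m) - 0.5) / sqrt(sigma2)
  z <- max(0, z)
  list(U = U, p_two_sided = min(1, 2 * stats::pnorm(-z)), method = "normal")
}

#' Express a running-condition mean as a percent of baseline
#'
#' Ratio convention: a value "increased to 245%" means
#' `100 * run / baseline = 245`.
#'
#' @param run_mean,base_mean means in the same units; `base_mean > 0`.
#' @return scalar percent.
#' @export
percent_of_baseline <- function(run_mean, base_mean) {
  if (!is_scalar_num(base_mean) || base_mean <= 0)
    stop_parameter("base_mean must be > 0")
  100 * run_mean / base_mean
}
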