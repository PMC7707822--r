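---
title: "Measuring locomotor-respiratory coupling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring locomotor-respiratory coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locoresp)
```

## The question and the measurement model

When a quadruped transitions from rest to running, breathing frequency
increases sharply. `locoresp` quantifies whether that faster breathing is
*phase-locked* to the stride: whether inspiratory bursts preferentially
start at a particular moment of the limb cycle. The measurement chain is:

1. **Diaphragm EMG to breath events.** The raw EMG is enveloped by a
   centered moving RMS; inspiratory bursts are detected by a hysteresis
   threshold search; consecutive bursts define respiratory cycles with
   inspiratory time Ti (burst duration), expiratory time Te (silence to
   the next burst), and instantaneous frequency `1/(Ti+Te)`.
2. **Pose tracks to stride events.** Side-view tracking of the four paws
   and the head (x, y, likelihood per frame) is cleaned, calibrated to cm,
   and resampled; each paw's forward motion is segmented into stance
   (ground contact) and swing by a velocity threshold; a footfall is the
   swing-to-stance touch-down, and consecutive footfalls of one limb
   delimit a stride cycle. Interlimb relative phases classify the gait
   (trot: hindlimbs alternate; gallop: hindlimbs synchronous, forelimbs
   alternate).
3. **Phases and verdict.** Each burst onset inside a stride cycle gets a
   phase in `[0, 1)`; the mean resultant length R of those phases measures
   concentration. A fixed criterion — oriented iff `R >= 0.3`, valid iff
   enough breaths were sampled (35 treadmill / 20 air puff) — gives the
   per-session verdict per reference limb. Analysis is restricted to
   *stable* running epochs, detected as windows where the head's
   horizontal coordinate neither drifts nor scatters (the animal keeping
   pace with the belt).

Key assumptions: the EMG channel is dominated by inspiratory diaphragm
activity (one burst = one inspiration); treadmill stance moves the paw
backward at belt speed in the camera frame; and the fixed-R criterion is
taken as given rather than replaced by a sample-size-dependent test (the
Rayleigh p-value `exp(-n R^2)` is reported separately, never substituted).

## Tunable parameters

All parameters live in `session_config()` (seconds, cm, Hz throughout).
The consequential ones:

* `integration_window` (0.015 s): RMS envelope window. Short enough to
  resolve a 40-60 ms running-breath burst, long enough to suppress
  carrier noise. Ti can only be recovered to within about this window.
* `k_mad` (5) and `threshold_mode` (`robust-baseline`): the burst
  threshold is `median + k_mad * MAD` of the envelope over a user-marked
  *quiet* epoch (`noise_epoch`, an expiratory silence). Marking genuine
  silence matters: statistics over an epoch containing rest breathing
  inflate the MAD and miss low-SNR bursts.
* `hysteresis_frac` (0.5): the burst closes when the envelope falls below
  `median + frac * (upper - median)`. The fraction applies to the
  supra-baseline elevation because an RMS envelope has a nonzero noise
  floor; a fraction of the absolute threshold can land below that floor
  and weld all bursts together. With `frac = 1` detection reduces to a
  plain super-threshold run scan.
* `min_Ti` (0.02 s) discards noise blips; `merge_gap` (0.005 s) bridges
  intra-burst envelope flicker. The merge gap must stay well below the
  shortest physiological expiratory pause (~15-20 ms at 8-11 Hz running
  breathing); a 30 ms gap, plausible at rest, silently welds a quarter of
  running breath boundaries and corrupts frequency estimates — measured,
  not hypothetical, which is why the default is 5 ms.
* `stance_frac` (0.25), `vel_window` (0.015 s), `min_stance`/`min_swing`
  (0.025 s): stance is where smoothed forward velocity is below
  `-stance_frac * belt_speed` (camera frame) or, overground, where speed
  is below `stance_frac * v_ref`. Footfalls/liftoffs are refined to the
  centroid of the sign-matching acceleration pulse, which is unbiased
  under symmetric smoothing; the raw threshold crossing is biased a few
  ms toward the later plateau, enough to distort duty factors at 10 Hz
  strides.
* `window_s` (6), `n_windows` (3), `skip_s` (20): respiratory summaries
  are means over a few 6-s windows placed deterministically (evenly
  spaced) in the run, skipping its first 20 s to avoid the startle
  transient. A run too short for one full window yields a truncated
  window plus a warning flag.
* `gait_tol` (0.15): circular tolerance around the ideal interlimb phases
  (0.5 alternation, 0 synchrony). Wide enough for jittered gaits,
  narrow enough that trot and gallop cannot overlap.
* `R_threshold` (0.3) and the validity minima are the fixed convention
  this analysis follows; both are config-exposed but changing them
  changes the science, not the engineering.

## What the synthetic generator emulates — and what it does not

`simulate_session()` produces pose tracks and EMG with known ground truth:

* **Gait**: one jittered master stride oscillator (multiplicative
  Gaussian cycle jitter, CV `cv_cycle`), with per-limb phase offsets —
  trot `rHL 0, lFL 0, lHL 0.5, rFL 0.5`; gallop
  `rHL 0, lHL 0.05, rFL 0.5, lFL 0.95`. Stance occupies the first `duty`
  fraction of each cycle with the paw moving backward at belt speed
  (sawtooth forward trace); swing returns the paw with a half-sine
  vertical lift. Tracking imperfections: Gaussian pixel noise and seeded
  likelihood dropouts with large position outliers, mimicking occasional
  paw misdetections at rest.
* **Breathing**: inspiration onsets from a hazard process
  `lambda(t) = lambda0 * exp(kappa * cos(2 pi (phi(t) - mu))) / I0(kappa)`
  with an absolute refractory of `0.6/f`; `lambda0 = 2.5 f` makes the
  mean rate exactly `f` when `kappa = 0` (the uncoupled null, giving
  uniform stride phases). Bursts are white-noise carriers under a
  linear-rise (80% of Ti) / sharp-release envelope, amplitude `snr` times
  the baseline noise SD. Breathing switches from `f_breath_rest` to
  `f_breath_run` at run onset.

Defaults describe a mouse trotting at 40 cm/s: stride 5 Hz, duty 0.6,
breathing 3.5 Hz at rest and 8 Hz running, Ti 45% of the breath cycle,
SNR 8, 200 fps video. The EMG rate defaults to 1 kHz — a pure time-base
scale-down of the 10 kHz acquisition typical of such recordings, chosen
for test runtime; every analysis step is rate-agnostic.

Two intrinsic properties of the coupled generator deserve note. First,
under strong coupling (`kappa = 8`) the stride cycle offers effectively
one firing window per cycle while the refractory forbids two breaths per
window, so the realized breath rate saturates near the stride rate
(1:1 locking) regardless of `lambda0`. Second, events fire on the rising
flank of the von Mises window (a first-passage effect), so the true mean
event phase sits about 0.05 cycles *early* of `mu` at `kappa = 8` with
the default rates. Both are reproduced exactly by an independent
renewal-kernel quadrature oracle in the test suite; tests of the
generator assert against that oracle, and end-to-end phase recovery is
judged against the programmed `mu` with a 0.05 tolerance that the
pipeline meets.

A green synthetic test therefore establishes that the pipeline recovers
what this generator produces: periodic gaits with camera-frame treadmill
kinematics, additive-noise EMG, and stationary coupling. It does not
establish robustness to electrode artifacts, gait transitions
mid-session, perspective distortion, fur occlusion, or non-stationary
coupling — real-data features the generator does not model.

## Numerical choices and degenerate inputs

* Half-open time convention everywhere: sample `i` covers
  `[t0 + i/fs, t0 + (i+1)/fs)`; an onset exactly at a footfall belongs to
  the cycle starting there; histogram bins are `[k/m, (k+1)/m)`.
* `circular_stats` flags the mean phase as `NA` when `R < 1e-9`
  (balanced phases leave the mean undefined).
* The RMS window is forced to an odd sample count so it is symmetric;
  edge windows shrink symmetrically.
* Burst definition: the maximal above-lower run that touches the upper
  threshold. Tying the onset to the lower (not upper) crossing keeps Ti
  estimates unbiased for ramped bursts; both conventions coincide at
  `hysteresis_frac = 1`.
* Mann-Whitney: exact two-sided p by full enumeration when the smaller
  sample has at most 8 values and there are no ties; otherwise normal
  approximation with tie and continuity corrections. Swapping samples
  maps `U -> n_a n_b - U` and leaves p unchanged.
* Cross-correlogram: signals are z-scored once; correlation at integer
  lags via zero-padded FFT with per-lag overlap normalization. The null
  envelope comes from circular time shifts of the second signal (each
  shift at least `max_lag`), which preserve autocorrelation. The band is
  `median +/- qnorm(1 - alpha/(4m)) * sd` per lag — a Bonferroni split of
  the family-wise `alpha/2` budget across the `m` lags. A naive per-lag
  5% band is escaped somewhere by almost every null realisation once a
  hundred lags are scanned; the family-wise band holds the false-alarm
  rate of the whole correlogram near `alpha/2` (measured 0.027 over 300
  white-noise pairs) and is conservative for smooth signals. Limitation:
  circular shifts of a strictly periodic signal reproduce its correlogram
  exactly, so a noiseless periodic signal against itself is reported flat;
  any aperiodic component restores detection.
* Seeding: a scenario is a pure function of its integer seed; surrogate
  shifts accept an explicit seed and restore the caller's RNG state.

## Open design choices

* **Footfall operator.** Nothing in the measurement convention dictates
  how footfalls are extracted from position traces. The
  velocity-threshold + acceleration-centroid design was chosen because it
  is frame-agnostic (treadmill camera frame or overground world frame,
  selected by `belt_speed > 0`) and achieves ~2 ms mean event error at
  200 fps against generator ground truth.
* **Quiet-baseline semantics.** The detection threshold's baseline epoch
  is a marked stretch of expiratory *silence*; the amplitude-normalization
  baseline is the whole pre-run rest period. The generator marks the
  longest inter-burst rest gap automatically, standing in for the
  experimenter's manual marking.
* **Per-animal value entering group statistics** is the mean of
  per-window means (not the grand mean over cycles), making animals with
  different cycle counts weigh equally.
* **Percent changes** follow the ratio convention:
  `100 * run / baseline`, so "increased to 229%" means a 2.29-fold rate.
* **Significance bands**: `*` for `0.01 <= p < 0.05`, `**` for
  `0.001 <= p < 0.01`, `***` for `p < 0.001`, `ns` above 0.05.

## Known limitations

* Ti is recoverable only to within the integration window; reported Ti
  at running rates is a few ms short of truth (ramped onsets cross the
  threshold late; the release crosses early).
* The stance detector needs a reliable reference speed; overground
  recordings without a usable head track cannot be segmented.
* Amplitude percent-of-baseline inherits envelope-peak bias: short
  bursts lose more peak to RMS smoothing than long rest bursts, so
  ~90% readings at equal programmed SNR are expected.
* No walk/bound/pace gaits; trials that are neither trot nor gallop are
  `undetermined` and excluded from gait-conditional summaries.
* The pipeline quantifies *phase* coupling only; frequency-ratio
  entrainment metrics are deliberately out of scope.
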