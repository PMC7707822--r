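# locoresp

Tools for asking a precise physiological question: **are breaths
phase-locked to strides in a running rodent?** During running, respiratory
rate roughly doubles; a long-standing hypothesis is that this hyperpnoea is
paced by the limbs — each breath triggered at a preferred moment of the
stride cycle, via visceral inertia or limb proprioception. Testing it
requires (i) breath timing from diaphragm EMG, (ii) stride timing from limb
tracking, and (iii) circular statistics linking the two.

`locoresp` implements that pipeline end-to-end for treadmill and corridor
recordings, plus a synthetic generator of coupled/uncoupled sessions so the
whole chain is testable without any animal data.

## The statistic at the core

Each inspiratory burst onset `t` falling inside a stride cycle
`[FF_{n-1}, FF_n)` of a reference limb receives a phase

    Phi = (t - FF_{n-1}) / (FF_n - FF_{n-1})  in [0, 1)

With `theta_i = 2 pi Phi_i`, the mean resultant vector

    C = mean(cos theta), S = mean(sin theta),
    R = sqrt(C^2 + S^2),  mean phase = atan2(S, C) / 2 pi  (mod 1)

has length `R = 0` for uniformly scattered phases (no coupling) and
`R = 1` for perfect phase locking. A mean phase is treated as significantly
oriented only when `R >= 0.3`, and a session's verdict is valid only with
enough breaths (35 on the treadmill, 20 in the air-puff context). A
first-order Rayleigh p-value `exp(-n R^2)` is available as a companion, and
surrogate-calibrated cross-correlograms provide a phase-free second look.

## Module map

| Stage | Functions |
|---|---|
| I/O | `read_timeseries`, `read_pose_table`, `read_session_config`, `write_result_tables` |
| EMG | `integrate_emg`, `detect_bursts`, `respiratory_cycles`, `normalize_amplitude`, `select_measurement_windows` |
| Kinematics | `clean_pose`, `resample_track`, `detect_stance_swing`, `relative_phase`, `classify_gait`, `stable_epochs`, `open_field_metrics` |
| Coupling statistics | `inspiration_phases`, `circular_stats`, `orientation_verdict`, `rayleigh_p`, `phase_histogram`, `cross_correlogram`, `mann_whitney_u` |
| Pipeline | `analyze_session`, `summarize_condition`, `compare_conditions`, `locoresp_cli` |
| Synthetic data | `sim_scenario`, `simulate_gait`, `simulate_breathing`, `simulate_session`, `write_session` |

## Worked example

Simulate an uncoupled treadmill trot session (stride 5 Hz, breathing
3.5 Hz at rest rising to 8 Hz while running, no breath-stride coupling) and
analyse it blind:

```r
library(locoresp)
sim <- simulate_session(sim_scenario(seed = 42, kappa = 0,
                                     duration = 40, rest_duration = 10))
res <- analyze_session(sim$emg, sim$tracks, sim$cfg)
res
#> <session_result> condition 'trot': 275 bursts, gait trot
#>   ref rHL  R = 0.038 (n = 237) -> not oriented
#>   ref lHL  R = 0.036 (n = 237) -> not oriented
#>   ref rFL  R = 0.037 (n = 237) -> not oriented
#>   ref lFL  R = 0.038 (n = 237) -> not oriented
round(res$summary$summary, 3)
#>       f      Ti      Te     amp amp_pct
#>   8.620   0.053   0.083   7.316  87.794
```

Reading the output: the gait was classified trot from the interlimb
phases; 237 inspirations fell inside stable-epoch stride cycles, their
phase concentration `R` is ~0.04 against every reference limb — far below
the 0.3 orientation threshold, so breaths show no stride-phase preference,
as programmed (`kappa = 0`). The windowed summary reports ~8.6 Hz mean
instantaneous breathing frequency during the run (inspiratory time 53 ms,
expiratory 83 ms). With `kappa = 8` the same call returns
`R ~ 0.95, oriented` with the mean phase near the programmed `mu`.

## Command line

```sh
locoresp simulate --scenario scenario.yaml --seed 3 --outdir session/
locoresp analyze  --emg session/emg.txt --pose session/pose.csv \
                  --config session/config.yaml --outdir out/
locoresp summarize --indir out/
locoresp compare  --a condA/ --b condB/ --param f
```

(the `locoresp` script is installed under `inst/cli/`; invoke it with
`Rscript $(Rscript -e 'cat(system.file("cli/locoresp", package="locoresp"))')`
or put it on your PATH). Exit code 0 on success, 2 on validation errors;
logs go to stderr.

See `vignettes/locomotor-respiratory-coupling.Rmd` for the model, the
parameter choices and their rationale, and known limitations.
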