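# fightphys

Exercise intensity and capture-stress physiology of longline-caught sharks.

Sharks caught on longlines alternate between struggling and resting while
hooked, and how hard an individual fights is thought to shape its
physiological status at landing. `fightphys` is an R package for
biologging-based capture-stress analysis: it classifies exercise intensity
from gangion-mounted 1-Hz tri-axial accelerometers, summarises each capture
event as exercise metrics, and models blood-based endpoints on exercise and
environmental covariates. It is aimed at conservation physiologists and
fisheries scientists working with hook-and-line or longline capture events.

## What it computes

1. **Vectorial sum.** Each sample of a tri-axial trace is reduced to
   `VS = sqrt(x^2 + y^2 + z^2)` (g) — robust to uncontrolled logger
   orientation on the gangion.
2. **Windowed features.** 30-s windows (50 % overlap) of the VS series give
   an amplitude (peak-to-trough range, g) and a cycle period (mean spacing
   of prominent local maxima, s).
3. **Intensity levels.** Per individual, windows are k-means clustered
   (k = 3) on standardized `(amplitude, log cycle)` and each cluster is
   assigned a level by its medians: **high** if amplitude > 0.25 g with a
   < 5-s cycle; **low** if amplitude < 0.05 g; otherwise **medium**
   (including strong but slow-cycle signal).
4. **Exercise metrics.** `p_low`, `p_med`, `p_high` — proportions of the
   event at each level (sum to 1 exactly) — and mean fight intensity, the
   summed VS over the event divided by the hook-timer capture duration
   (g min^-1).
5. **Models.** Each blood endpoint (pH, lactate, glucose, haematocrit,
   Na+, K+, Cl-, Ca2+) is regressed on logit-transformed `p_low`, capture
   duration, SST and total length by complete-case OLS, per species. 95 %
   intervals come from 1000 noninformative-prior posterior simulations
   (draw the residual variance from its scaled inverse-chi-square
   posterior, then coefficients from the corresponding multivariate
   normal); a term is significant iff its interval excludes zero.
6. **Panel preparation.** Optional linear temperature correction of 37 °C
   pH to SST, panel validation that preserves missingness, and a
   hyperkalemia flag (K+ > 7.0 mmol l^-1, strict).

A seeded synthetic generator (`simulate_capture_event()`,
`simulate_physiology()`, `simulate_study()`) produces capture events with
known per-second intensity labels — Markov bout structure, front-loaded
struggling, logger quantization (0.025 g) and clipping (±3 g) — and blood
panels with known coefficients calibrated to published descriptive
statistics for nurse and Caribbean reef sharks, so the whole chain can be
validated against ground truth.

## Worked example

```r
library(fightphys)

dir <- file.path(tempdir(), "demo"); out <- file.path(dir, "out")
simulate_study(12, bout_model_config(duration_range_min = c(10, 120)),
               nurse_physio_config(), seed = 2024, dir = dir)
res <- run_pipeline(pipeline_config(
  deployment = file.path(dir, "deployment.csv"), accel_dir = dir,
  out_dir = out, responses = c("ph", "glucose"), n_sims = 1000, seed = 2024))

head(res$metrics[, 1:6], 4)
#>   event_id p_low p_med p_high capture_duration_min mean_fight_intensity
#> 1    ev001 0.686 0.224 0.0897                 33.5                 62.5
#> 2    ev002 0.529 0.406 0.0652                 34.5                 63.1
#> 3    ev003 0.456 0.372 0.1723                 71.9                 64.7
#> 4    ev004 0.374 0.478 0.1478                 79.5                 64.6
```

Shark `ev001` spent 69 % of its 33.5-min capture event at low intensity and
9 % at high intensity; its mean fight intensity of 62.5 g min^-1 sits just
above the ~60 g min^-1 floor a motionless 1-g logger would register. The
model report (also written to `out/model_report.csv` and `.txt`):

```r
writeLines(format_significance_table(res$table))
#> species         response     term                     estimate       2.5%      97.5%  sig
#> -----------------------------------------------------------------------------------------
#> nurse           ph           (Intercept)                7.0698     5.8678     8.0454    *
#> nurse           ph           p_low_lr                   0.0361    -0.0673     0.1454
#> nurse           ph           capture_duration_min       0.0008    -0.0019     0.0038
#> ...
```

At n = 12 sharks no covariate clears the interval-excludes-zero bar — the
`*` marks significant terms; at the calibrated field sample size (n = 35)
the positive pH effects of `p_low` and duration are recovered in most
simulated studies (see below). Per-second labels are in `res$labels`, and a
run log with versions and seeds is written alongside the outputs.

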