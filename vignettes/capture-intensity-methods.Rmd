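---
title: "Methods: exercise-intensity classification and capture-stress models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exercise-intensity classification and capture-stress models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fightphys)
```

## The problem

Sharks hooked on longlines alternate between struggling and resting, and the
intensity of that exercise is thought to shape their physiological state at
landing — acid–base status, lactate, glucose, haematocrit and plasma ions.
`fightphys` implements the full analysis chain for this question: it turns a
1-Hz tri-axial accelerometer trace recorded on the gangion into per-second
exercise-intensity levels, summarises each capture event as exercise metrics,
and relates blood endpoints to those metrics and to environmental covariates
with linear models whose intervals come from posterior simulation. Because
field data of this kind are rarely shared, the package also ships a seeded
synthetic generator that produces capture events with *known* per-second
intensity and blood panels with *known* coefficients, so every stage can be
validated end-to-end.

## From acceleration to intensity levels

**Vectorial sum.** Each sample is reduced to its magnitude
$VS = \sqrt{x^2 + y^2 + z^2}$ (in g). The magnitude is used rather than a
dynamic-body-acceleration decomposition because hooking orientation cannot be
standardised across animals; a motionless logger reads 1 g regardless of
orientation.

**Windowed features.** The VS series is tiled with 30-s windows at 50 %
overlap. Per window we compute

* `amplitude_g` — the peak-to-trough range $\max(VS) - \min(VS)$. Range is
  deliberate: it is translation-invariant, so the ~1 g static baseline drops
  out and a 0.05-g threshold is meaningful. This definition is the package's
  operationalisation; field protocols often leave "amplitude" undefined.
* `cycle_s` — the mean spacing of local maxima of the mean-removed signal.
  Peaks must clear a prominence of `max(0.25 * amplitude, 0.05 g)`. The
  relative threshold rejects ripple on large signals; the absolute floor of
  two logger quanta (2 x 0.025 g) keeps quantization noise in near-static
  windows from producing spurious fast cycles, which would otherwise place
  resting windows near struggling windows in feature space. Windows with
  fewer than two qualifying peaks get the sentinel `cycle_s = window_s`
  (correctly treated as "slow" downstream). Cycles estimated below 2 s are
  floored and flagged: 1-Hz sampling cannot resolve them.

The 30-s default window resolves both the <5-s cycles of burst swimming and
slower tail-beat cycles while still tracking bout changes; 10 s is the
enforced minimum at 1 Hz.

**Per-individual clustering and cutoff rules.** Features
`(amplitude, log cycle)` are z-scored *within* each individual and clustered
with k-means (k = 3, multiple restarts, seeded). Clustering per individual
avoids biases from pooling animals with different baseline activity.
Clusters are then mapped to levels by their **median** amplitude and cycle:

* **high** — amplitude > 0.25 g *and* cycle < 5 s;
* **low** — amplitude < 0.05 g;
* **medium** — everything else, including large-amplitude slow-cycle signal.

All inequalities are strict; boundary values fall to medium, the
conservative middle. Applying the rule to cluster medians (not single
windows) mirrors the cluster-then-assign field protocol and avoids label
chatter; a per-window mode is available via `assign_levels(mode = "window")`.
If an individual shows fewer than k distinct feature points, k collapses
with a warning — not every animal exhibits all three levels. Cluster indices
are relabelled by ascending centroid amplitude, so output never depends on
k-means' arbitrary ordering.

**Per-second labels and metrics.** Windows are expanded to seconds in start
order with later windows overwriting earlier ones; trailing seconds inherit
the last window's level. Exercise metrics per event: `p_low`, `p_med`,
`p_high` (proportions of labelled seconds; `p_high` is computed as the
complement of the rounded `p_low + p_med` so the three sum to 1 *exactly* in
floating point) and `mean_fight_intensity` — the sum of VS values over the
event divided by the hook-timer capture duration, in g min^-1. Duration
always comes from the hook timer, not the trace length, since loggers record
before hooking and after landing; optional trimming is left to the caller.

## Physiological endpoints

Point-of-care analysers measure pH at 37 °C. `correct_ph()` defaults to
identity and accepts a linear correction
`pH = pH37 + slope * (37 - SST)`; the historical species-independent
conversion equations are published elsewhere and their coefficients must be
supplied by the user — the package does not guess them, and current best
practice is the analyser's own temperature correction anyway.
`flag_hyperkalemia()` flags plasma potassium strictly above 7.0 mmol l^-1,
the threshold associated with tetany and mortality risk in captured
elasmobranchs; a missing potassium yields a missing flag, never `FALSE`.
Validation rejects impossible panels (negative concentrations, haematocrit
outside 0–100 %) but preserves missingness — nothing is imputed.

## Statistical models

Because the three proportions sum to one, `p_low` enters the models on a
log-ratio scale. The default is the logit, `log(p / (1 - p))` — low versus
not-low, the natural binary split when only `p_low` is analysed — with an
additive-log-ratio alternative `log(p_low / p_high)` behind
`transform = "alr"`. Proportions are clamped by `eps = 1e-6`, or by the
half-count rule `1/(2 n_seconds)` when the event length is known.

Each endpoint is fit by complete-case OLS on the study's four covariates
(transformed `p_low`, capture duration in min, SST in °C, TL in cm),
unstandardised, so intercepts stay on the measurement scale. Per-endpoint n
varies with missingness, as in real panels. Inference uses
noninformative-prior posterior simulation (1000 draws by default): each draw
takes $\sigma^{*2} = \mathrm{df}\, s^2 / \chi^2_{\mathrm{df}}$ and then
$\beta^* \sim N(\hat\beta, \sigma^{*2} (X'X)^{-1})$; the reported interval
is the empirical 2.5/97.5 % band and a term is "significant" iff the band
excludes zero. No multiple-testing correction is applied across the eight
endpoints — a deliberate caveat, matching common practice in this
literature. The marginal draw distribution is exactly a scaled-t, so at
large n the intervals coincide with classical t intervals; the test suite
checks both that agreement and the empirical coverage/type-I behaviour.

## The synthetic generator

`simulate_capture_event()` draws a capture duration uniformly on
2.57–264.88 min (the span observed in the emulated field protocol, which
capped sets at 4.5 h), then a hidden per-second level sequence:

* an optional **front-loaded struggle** — a single initial high-intensity
  bout of Exp(180 s) duration, on by default. Hooked sharks are described
  as struggling immediately after hooking and settling thereafter; this is
  also what makes mean fight intensity decline with capture duration.
* a base Markov chain with mean dwells of 600 s (low), 180 s (med), 90 s
  (high). These dwells are the package's choice — the field literature
  reports no bout-length distributions — picked as realistic for a
  resting-prone species (resting stretches of many minutes, brief bursts)
  and long relative to the 30-s window so that behaviour is resolvable at
  the sensor's resolution.

Within a bout the VS signal is
`baseline + range * (1 - cos(2*pi*t/period)) / 2` with range and period
drawn per bout from level-specific normals: amplitude means 0.02 / 0.15 /
0.60 g (sd 0.005 / 0.03 / 0.10), cycle means 10 / 7 / 3 s. The means
straddle the 0.05 and 0.25 g cutoffs with wide margins (separation >= 3
within-level sd) and are flagged as uncalibrated: the source protocol
reports only the cutoffs. The one-sided oscillation (bursts raise mean
magnitude above baseline) reflects how thrashing rectifies into a magnitude
signal. The target VS is projected onto a fixed random unit orientation per
event, and each axis is quantized to 0.025 g and clipped to +-3 g.

`simulate_physiology()` inverts the fitted models: endpoint = linear
predictor + Gaussian noise, with concentrations floored at zero (detection
floor). Shipped calibrations (`nurse_physio_config()`,
`reef_physio_config()`) set intercepts and residual sds so that simulated
means and spreads approximate the published descriptive statistics of each
species, with nonzero slopes only for the effects that study reported as
credible (e.g. pH increasing with transformed `p_low` at 0.065 per logit
unit and with duration at 8e-4 per min for nurse sharks). Residual sds come
from decomposing the reported total sds; coefficients sit at the midpoints
of the reported interval bounds.

What the generator does **not** emulate: hydrodynamic or biomechanical
waveforms (real tail beats are not cosines), logger mounting compliance,
hook-timer failure, gear checks every 30 min, tidal/diel covariate
structure, or correlated covariates (SST, TL, duration and `p_low` are drawn
independently). Passing recovery tests therefore demonstrates internal
consistency of the pipeline under a plausible signal model, not field
performance.

## Numerical and design choices

* **Seeding.** Every stochastic component draws from a stream derived from
  one master seed (`derive_seed()`), so e.g. changing `n_sims` never
  perturbs simulated traces, and identical configs give byte-identical
  pipeline outputs.
* **Boundary seconds.** With 50 % overlap and later-window-wins, each second
  is labelled by the window in whose first half it falls; mislabelling is
  confined to within one window of a bout boundary, which is what bounds the
  per-second error on long-dwell events.
* **Degenerate inputs.** Constant windows get amplitude 0 and the no-cycle
  sentinel; events shorter than one window become a single full-trace window
  with a warning; k-means collapses k for degenerate feature sets; models
  refuse rank-deficient designs and n below terms + 2, naming the offender.
* **Validation problem sizes.** The shipped validation (tests and
  `scripts/acceptance.R`) uses 40 full events for label recovery, 100 random
  datasets for the OLS oracle, 500 replicates for coverage and type-I
  behaviour, and 200 studies (n = 35, or 20 full traces) for the
  qualitative-pattern checks — sizes chosen to make Monte-Carlo error small
  relative to the tolerances being asserted.

## Known limitations

Windowed features cannot resolve bouts much shorter than the window, so
per-second accuracy degrades on highly fragmented behaviour; 1-Hz sampling
cannot resolve cycles below 2 s; the log-ratio reference part (logit vs alr)
is a modelling choice the user can flip; and the pH correction is pluggable
rather than built-in. The statistics are deliberately plain OLS — no mixed
effects, GLMs or model selection — matching the analysis the package
reproduces.
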