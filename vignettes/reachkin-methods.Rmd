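---
title: "reachkin: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{reachkin: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`reachkin` analyses goal-directed reach-and-place movements recorded as
3-axis wrist displacement at a fixed sampling rate (100 Hz by default, the
usual rate of wrist-worn IMU systems). From each trial it extracts twelve
kinematic parameters in common use in developmental motor control:

* **reaction time** — go signal to movement onset;
* **movement time**, **total distance** — duration and Euclidean path length
  of the movement window;
* **average / maximum velocity** and **time to peak velocity** — from the
  speed series (norm of the velocity vector);
* **average / maximum acceleration** and **time to peak acceleration** —
  from the acceleration-vector magnitude;
* **movement units, Types 1–3** — zero-crossing counts of velocity,
  acceleration and jerk, counted per axis (x, y, z) and consolidated as
  RMS = sqrt((nx² + ny² + nz²)/3). More units indicate more corrective,
  less smooth movement.

Downstream, the package reproduces a typical analysis of such features in a
two-child-group (TD vs ASD) plus adult-reference design: Mann-Whitney U
group comparisons with Levene/KS assumption checks, Pearson correlations of
kinematics against adaptive-functioning scores with Benjamini-Hochberg FDR
flags, and a small MLP classifier evaluated by stratified ten-fold
cross-validation with permutation feature importance.

Because the human recordings such analyses are run on are generally not
redistributable, the package ships a generative model of the task
(`simulate_cohort()`) with full ground truth, and every pipeline stage is
tested against that generator.

# The synthetic trial model

A trial is a superposition of minimum-jerk submovements on a quiescent
baseline:

1. **Pre-go baseline** (0.5 s) and a **reaction-time delay** drawn from the
   group profile (truncated normal, floor 0.08 s).
2. A **primary reach** following the minimum-jerk profile
   x(τ) = A(10τ³ − 15τ⁴ + 6τ⁵). Its closed forms anchor the extractor
   tests: peak speed 1.875·A/T at τ = 1/2, peak |acceleration|
   (10/√3)·A/T² at τ = (1 − 1/√3)/2. A piecewise-linear warp of τ moves the
   speed peak to `time_to_peak_fraction` of the movement time while keeping
   both endpoints at rest — this is how "prolonged time to peak
   velocity/acceleration" is generated without changing the amplitude.
3. An **overshoot-and-return** excursion (out and back along the reach
   direction) contributing extra path `overshoot_fraction × A`.
4. A Poisson number of **corrective submovements**: small minimum-jerk
   bumps in alternately perturbed directions, overlapping in time, which
   create the extra zero-crossings that movement-unit counts measure.
5. **Additive white positional noise** (default SD 5e-6 m).

Subject-level random effects (lognormal on timing/amplitude means, ~8–10%
CV; additive on the peak-time fraction) are drawn once per subject so that
trials within a subject are correlated — deliberately reproducing the
subject-leakage issue that trial-level cross-validation folds admit.

## What the generator's defaults state

The default profiles encode *effect directions*, not any study's group
means: relative to TD children, the ASD profile reaches farther (0.36 vs
0.23 m), overshoots more (0.20 vs 0.06), makes more and larger corrective
submovements (Poisson mean 4.0 vs 1.0; 12% vs 6% of amplitude), peaks later
(peak fraction 0.50 vs 0.42) and reacts borderline-slower (0.50 vs 0.45 s).
Adults reach farther and longer but react faster and peak earlier. Group
sizes default to 15 TD and 26 ASD children (×6 trials, i.e. a 156/246 ≈ 65%
ASD trial mix) plus 10 adults.

Two generator constants were calibrated once against the direction-recovery
requirement (all eight ASD-greater directions significant at p < 0.05 in
≥ 18/20 seeds) and then frozen:

* **Noise 5e-6 m.** Zero-crossing counts of band-limited noise are
  amplitude-independent, so at realistic raw-sensor noise levels the unit
  counts measure noise time rather than corrective dynamics — and smoother
  trials (more quiet time) then count *more* units, inverting the group
  direction. The default therefore represents displacement after vendor
  sensor fusion, where residual noise sits below the 1%-of-RMS hysteresis
  band and unit counts measure corrections. This is the main respect in
  which the generator is cleaner than raw field data; a green
  direction-recovery test establishes that the pipeline recovers the stated
  world's structure, not that raw unfused IMU data would behave as well.
* **Overshoot/corrective separation** between the child profiles, sized so
  the maximum-acceleration and Type-2 directions survive subject-level
  sampling variability at n = 15 vs 26.

The generator does not model: biomechanics (joint limits, muscle dynamics),
the partner's mirrored movements, block-to-block structure within the
continuous trial, instruction effects, or realistic trial exclusion
(`dropout_rate` exists but defaults to 0).

# Extraction choices

**Smoothing.** Positions are low-pass filtered before differentiation:
zero-phase (forward-backward) 4th-order Butterworth, 10 Hz cutoff at
100 Hz. Reaching energy lies well below 10 Hz while double/triple
differentiation amplifies noise quadratically/cubically in frequency;
zero-phase filtering adds no group delay, so onset and time-to-peak
estimates are not shifted. `filter_spec("none")` disables smoothing for
analytic fixtures. The filter design was validated coefficient-for-
coefficient and output-for-output against an independent reference
implementation.

**Onset.** The onset rule thresholds both the relative distance from the
go-signal position and the acceleration magnitude at 20% of their
search-window maxima. Applied literally ("first sample where both hold"),
this dates initiation where a fifth of the reach distance is already
covered — about a third of the movement time into a smooth reach — which
misattributes path and time. The default (`onset_refine = "burst_start"`)
therefore keeps the dual-threshold detection but walks the detected sample
back along the monotone rise of the distance excursion to where motion
begins; on noiseless fixtures this recovers the true start exactly, and
reaction time within 2 samples across random profiles. The literal rule
remains available (`onset_refine = "none"`).

**Movement end.** Trials in this task family are experimenter-terminated,
so the recording end delimits the movement window by default
(`end_rule = "recording_end"`); a 5%-of-peak-speed trimming rule is
available for single-reach analysis.

**Zero crossings.** A crossing is a move from above +h to below −h (or vice
versa) with h = 1% of the series RMS; excursions inside the band do not
count, exact zeros resolve to the next signed sample, and h = 0 reproduces
the literal sign-change rule (verified against a brute-force oracle on
1,000 random signals). The hysteresis keeps counts stable under residual
noise.

**Averages.** Average velocity/acceleration use the trapezoidal time
average of the speed / |acceleration| series (half-weight endpoints), which
equals distance/time on closed-form fixtures; a plain sample mean carries a
small endpoint bias. Acceleration statistics use the magnitude of the
acceleration vector; signed per-axis alternatives were rejected for
sign-convention ambiguity. Ties at the maximum resolve to the first
occurrence.

**Common frame.** `to_common_frame()` translates the start to the origin
and rotates the first principal axis of the trajectory onto +X (sign chosen
so net displacement is non-negative; right-handed completion). All twelve
summary features except the per-axis crossing counts are rotation-invariant
and are verified unchanged (±1e-6 relative) under random rigid rotations;
per-axis counts before RMS consolidation are convention-dependent and are
flagged as such.

# Statistics

Group comparisons use the two-sided Mann-Whitney U test (midranks; exact
enumeration of all rank assignments for tie-free samples with n₁+n₂ ≤ 12,
otherwise the normal approximation with tie and continuity corrections),
with Brown-Forsythe Levene and a fitted-normal KS check attached as
assumption diagnostics. The unit of analysis is configurable: trial-level
(pooled trials, the larger-n protocol) or subject means (statistically
cleaner; trials within a subject are not independent).

Correlation tables compute Pearson r with t-distribution p-values between
kinematics and per-subject covariate scores, by default at trial level with
the subject's score broadcast to its trials (reproducing the pooled-n
design in which r ≈ 0.24 can reach p < 0.001); a subject-level option is
provided. FDR control is Benjamini-Hochberg, applied within each
covariate × group column family — the FDR family is a genuinely open choice
and per-column matches how such tables are column-wise starred.

# The classifier protocol

Nine of the twelve parameters (all but movement time and Type-1/Type-3
units) feed a fixed MLP: 9 → 64 → 32 → 16 → 1, four fully connected
layers, batch normalization then leaky ReLU (slope 0.01) after each hidden
layer, sigmoid output, binary cross-entropy, ADAM. The learning rate starts
at 1e-5 and drops permanently to 1e-6 once per-epoch training accuracy
(evaluation mode) reaches 95%; training runs 200 epochs with mini-batches
of 32, and the parameter state at the minimum validation loss is kept.
Features are min-max normalized over the entire dataset by default — a
protocol-faithful choice that leaks fold information; a per-training-fold
variant (`normalize = "fold"`) is provided and flagged in outputs.

Unstated details resolved as package design choices: hidden widths 64/32/16
(tapering capacity adequate for 9 features and a few hundred samples); BCE
loss (implied by the sigmoid output); leaky slope 0.01; batch norm placed
after each hidden linear layer, before the activation; 0.5 decision
threshold; the 95% switch evaluated per epoch; hidden weights He-normal and
the **output layer zero-initialized** — with cumulative parameter movement
of order epochs × lr, a randomly initialized output layer leaves initial
random logits the schedule cannot overcome, whereas zero initialization
starts the decision exactly at chance and classification correctness then
depends only on the sign of the learned direction. Accuracy is reported
alongside per-fold sensitivity/specificity because a ~65/35 class mix makes
raw accuracy optimistic.

Cross-validation is stratified ten-fold at trial level (the replicated
protocol) or subject level (`grouping = "subject"`, the recommended
scientific default: subject random effects otherwise leak between folds,
and the suite verifies that subject-grouped accuracy does not exceed
trial-level accuracy on cohorts with subject effects). Permutation
importance shuffles one validation column at a time (20 repeats), scoring
mean permuted loss minus the recorded best validation loss, per fold and
averaged.

# Numerical and testing notes

* Exact-enumeration vs normal-approximation Mann-Whitney p agree within
  0.02 for per-group sizes ≥ 6 (verified exhaustively at 6 vs 6 over all
  achievable U; the bound is false for 3 vs 3, where the worst deviation is
  0.0375).
* The all-null empirical FDR of BH equals q in expectation exactly, so the
  simulation check allows the 99% binomial Monte-Carlo margin around q
  rather than asserting a hard ≤ q.
* Twice-applied central differences attenuate a 1 Hz sinusoid at 100 Hz by
  0.13%; tests assert 0.2%.
* All randomness is seed-threaded (`with_seed` restores the caller's RNG
  state); cohorts, training runs and pipeline artifacts are byte-identical
  under a fixed seed.
* Degenerate inputs: motionless trials raise a no-movement error and are
  dropped (with a log) by the batch extractor; zero-path trajectories are
  translated only, with a warning; constant features normalize to zero with
  a warning; constant samples make the rank tests return p = 1 with a
  degenerate flag.

# Known limitations

The generator's cleanliness (low noise, no artifacts, no exclusions) means
green tests certify pipeline correctness on the stated world, not
field-data robustness. The classifier's schedule-faithful small learning
rates mean decisions ride on small-magnitude logits; reported probabilities
are close to 0.5 and should be read as rankings, not calibrated risks. The
headline accuracies of the motivating study are properties of its
non-deposited human data and are intentionally not reproduction targets.
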