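---
title: "Continuous tracking analysis of oculomotor function: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous tracking analysis of oculomotor function: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sondar)
```

This vignette explains the models, assumptions, parameter choices and known
limitations behind `sondar`. The package analyzes gaze recorded while a
participant follows a continuously moving blob, in two modes: *smooth
pursuit* (the blob moves continuously with pseudo-randomly varying heading
and speed) and *saccadic pursuit* (the same motion, plus discrete jumps to
locations sampling the visual field). The design goal throughout is that
every stage is runnable and testable on synthetic data with known ground
truth, because clinical recordings are not distributable with the package.

## Display geometry and units

All analysis is done in degrees of visual angle with a center origin,
rightward and upward positive. The default geometry is a 24.5-inch,
1920 × 1080 monitor at 60 cm, refreshing at 240 Hz; square pixels are
assumed, so physical width and height follow from the diagonal and the
resolution aspect ratio. Angular extents use the exact arctangent (not the
small-angle approximation): at this geometry the screen subtends 49° × 29°,
and the wide horizontal extent is exactly where the small-angle
approximation would be off by more than a degree. Per-pixel conversion maps
each pixel column/row through its own local tangent, making
`pixels_to_degrees()`/`degrees_to_pixels()` exact inverses.

One frame at 240 Hz is the time quantum of the analysis: delays in the
tracking statistic move in steps of 1/240 s ≈ 0.0042 s, and the tolerated
gaze/stimulus length mismatch of 0–2 frames corresponds to at most 8.33 ms.

## The tracking statistic

Tracking performance for one trajectory and axis is computed from the
time-shifted cosine similarity between the stimulus position vector $A$ and
the gaze position vector $B$:

$$\mathrm{cossim}(A, B) = \frac{A \cdot B}{\lVert A\rVert\,\lVert B\rVert}$$

evaluated at every delay from −5 to +5 s in one-frame steps. A positive
delay $d$ compares $A_i$ with $B_{i+d}$: gaze lagging the stimulus. The
performance is the value at the *first local maximum at positive delay*
(strictly greater than both neighbours; a plateau counts at its first
sample; no prominence threshold); if the function has no positive-delay
peak — typical of very poor tracking — the maximum over delays in
$(0, 3]$ s is used instead and flagged (`peak_found = FALSE`). The upper
edge of the fallback window is inclusive.

Two numerical choices deserve comment:

* **Centering.** The similarity is computed on center-origin degree
  coordinates. Raw top-left pixel coordinates carry a large positive offset
  common to both vectors, which drives the cosine toward 1 regardless of
  tracking quality; centering restores the metric's discriminative range.
  Trajectories start at the screen center, so the centered signals are
  mean-zero-ish by construction.
* **Missing data.** Masked (NaN) samples are handled by pairwise-complete
  deletion inside each delay's overlap window. This preserves sample order
  and adds no interpolation artifacts; it requires at least two complete
  pairs, otherwise the similarity is undefined and treated as missing at
  that delay.

Saccadic-mode performance averages the three saccadic trajectories of a
set; binocular performance is computed per eye and then averaged; axes are
always reported separately.

## Pre-processing

Gaze is recorded at 1000 Hz and the stimulus at 240 Hz. The chain is:

1. **Down-sampling** by nearest-sample selection at each frame time. No
   anti-alias filter is applied: selection preserves the sharp position
   edges that saccade analysis needs, and a 1 Hz test sinusoid survives
   with < 1% amplitude error.
2. **Length reconciliation**: the gaze vector may exceed the stimulus
   vector by 0–2 frames (recording timing slop); the excess is trimmed from
   the end. Larger discrepancies are an error, not silently repaired.
3. **Unreliable-period detection**: (a) 2-D point-to-point speed above
   750 deg/s (both endpoints of the offending step are flagged) — faster
   than any real eye movement; (b) position plateaus, the signature of the
   acquisition system repeating the last known position during tracking
   loss. "Zero velocity for at least two consecutive samples" is read as at
   least two consecutive zero-velocity *steps* (≥ 3 bit-identical
   positions), because single repeated samples can occur legitimately at
   240 Hz while hold-fill runs are long; a strict single-step reading is
   available via `plateau_steps = 1`. Plateau comparison uses exact
   floating equality on purpose — hold-fill repeats values bit-identically.
   A per-axis variant of the velocity check is available (`per_axis`).
4. **Masking**: each flagged run, padded by 0.05 s (12 frames) on each
   side, becomes NaN. Masking is idempotent: NaN steps are neither velocity
   peaks nor plateaus.
5. **Discard rules**: a trajectory more than half NaN is discarded; a
   discarded smooth trajectory excludes the (single-trajectory) smooth part
   of its set; two or more discarded saccadic trajectories exclude the
   saccadic part.

## Saccade analysis

Saccades are taken either from EyeLink-ASCII `ESACC` lines (positions in
pixels, converted through the display geometry; malformed lines are skipped
and counted, missing-data tokens drop the event) or from the package's own
velocity/acceleration parser: an event opens when smoothed 2-D velocity
exceeds 30 deg/s or acceleration exceeds 8000 deg/s², closes when both fall
below, and events closer than 20 ms merge. Velocity is a Savitzky–Golay
quadratic local derivative; the default window is 21 ms, wide enough that
drift-like positional noise of 0.3° SD stays well under the 30 deg/s
threshold while the peak of a 2° saccade (≈ 170 deg/s) is preserved. The
window is a parameter (`deriv_window`) for data with different noise
character. Amplitude is recomputed from the event endpoints by default
(`trust_amplitude = TRUE` keeps the parsed value).

The six filter rules (amplitude > 50° or < 2°, duration < 10 ms or
> 150 ms, peak velocity > 750 deg/s, endpoint off screen) are strict
inequalities, so boundary events are retained; an event failing several
rules is counted once under the first failing rule, in that order.
Orientation is vertical for angles in $[45°, 135°) \cup [225°, 315°)$ and
horizontal otherwise — half-open intervals guarantee a partition; exact
boundary angles are measure-zero in real data.

The main sequence is modelled as peak velocity linear in amplitude:

```
peak_velocity ~ amplitude_c * group * viewing + age + bcva + (1 | participant)
```

with amplitude centered on the grand mean, so the intercept is the peak
velocity at the mean amplitude. Residuals of such models are routinely
non-normal (checked with Shapiro–Wilk; the test's 5000-observation limit is
handled by deterministic subsampling), so confidence intervals come from a
bootstrap — parametric at the fitted model by default, with a
participant-level cluster bootstrap (`type = "cluster"`) and basic CIs
(`ci_method = "basic"`) as alternatives; the default is percentile CIs from
5,000 replications. A term is called significant when its 95% CI excludes
zero. The bootstrap seed is stored in the fitted object.

## Group statistics

Each outcome (tracking performance, absolute positional difference, median
saccadic amplitude) is compared between groups with OLS regression on a
group indicator plus age and BCVA, separately per viewing condition, axis
and pursuit mode. p-values are Benjamini–Hochberg FDR-adjusted *within one
family per outcome table* (8 tracking tests, 4 positional-difference tests,
4 amplitude tests in the full design): this reproduces the natural
reporting structure, and the family map is the place to change if a
different partition is wanted. Demographics use two-sided Mann–Whitney U
tests with tie correction.

## Binocular synchronization

The per-sample difference is OD − OS per axis (NaN if either eye is NaN),
averaged over the trajectory, then over the three saccadic trajectories.
The phrase "absolute positional difference" is ambiguous between the
absolute value of the trajectory mean and the trajectory mean of absolute
values; the package defaults to **|trajectory mean|**, because differences
are described as being averaged first, and exposes the per-sample variant
(`per_sample_absolute = TRUE`). The two differ exactly when the difference
changes sign within a trajectory — both are tested, and for a constant
disconjugacy they agree.

## The synthetic-data generator

The generator exists to give every pipeline stage input with known ground
truth; its defaults describe the experimental conditions the analysis
expects.

* **Stimulus.** Smooth trajectories are a smoothed random walk on heading
  with a mean-reverting speed process (mean 8 deg/s, max 15 deg/s, one step
  per frame), steered back toward the center near the screen edge, starting
  at (0, 0). The speed statistics of the original stimulus are not
  published, so these are the package's own choices, exposed as parameters.
  Saccadic trajectories add 18 jumps per 40 s (uniform spacing, ±20%
  jitter) to targets from a 54-point, 6°-spaced Humphrey 24-2-style grid
  scaled to fit the screen; the three saccadic trajectories of a set
  partition the grid, so one set samples every location exactly once.
* **Gaze.** The deterministic trace is a pursuit component — the smooth
  stimulus component delayed by `pursuit_delay_s` and scaled by
  `pursuit_gain` — plus a saccadic response to each jump: after
  `saccade_latency_s`, saccades each cover `hypometric_gain` of the
  remaining error, stopping below 1° of error (under the 2° analysis
  threshold) or at `max_saccades_per_jump`, after which the residual decays
  with a 0.3 s pursuit time constant. Saccade waveforms are raised-cosine
  in velocity — symmetric, with duration fixed by amplitude/peak-velocity
  consistency ($D = 2A/V_p$) — and peak velocities follow the linear main
  sequence $V_p = V_{\bar A} + s\,(A - \bar A)$ anchored at 6.5°. The
  healthy preset uses delay 0.15 s, gain 1, noise SD 0.3°, latency 0.15 s,
  hypometric gain 0.9 with at most 2 saccades; the case preset uses
  hypometric gain 0.4 with up to 5 saccades, a 1.4° horizontal OD−OS
  offset, and a steeper main sequence (18.6 deg/s/deg).
* **Noise and artifacts.** Positional noise is white noise smoothed over
  200 ms and rescaled — drift-like, concentrating power below a few Hz.
  Broadband white noise of 0.3° SD at 1000 Hz would be physically
  unrealistic and would make any velocity-threshold parser unusable, so the
  band limit is part of the noise model, not a tuning knob. Blinks are
  Poisson events (healthy preset: 0.1 Hz, 0.15 s) during which `tracked`
  is FALSE and the recorded position repeats the last tracked value
  bit-identically — exactly the artifact the plateau detector removes. In
  binocular mode the OS trace is the OD generative trace minus the
  disconjugacy offset plus independent noise.
* **What it does not emulate.** Pupil dynamics, torsion, nystagmus
  waveforms, calibration error fields, glissades/post-saccadic
  oscillations, and main-sequence saturation at large amplitudes (the
  linear model is the analysis model, so the generator stays within its
  range). Passing tests on synthetic data therefore demonstrate the
  *analysis machinery*, not robustness to every artifact of real
  recordings.

All generators and the simulator are pure functions of their seeds, and
they save/restore the caller's RNG state.

## Problem sizes and test design

The test suite runs the full 40 s × 240 Hz geometry where the claim depends
on it (ceiling performance, self-similarity) and 5–12 s trajectories where
it does not, keeping the suite fast. Parameter-recovery checks fit the
mixed model on 60 participants × 100 saccades with 500 bootstrap
replications — the CI widths at that size are a fraction of the effects of
interest. Because a 95% CI excludes its target in about 5% of replicates by
construction, the recovery test uses three independent cohorts and requires
containment in at least two; under correct coverage this fails less than 1%
of the time, while a genuinely biased estimator still fails reliably.

## Known limitations

* The exact smoothing used by the proprietary EyeLink parser is
  unpublished; the package's detector is a conventional
  velocity/acceleration parser and will not reproduce ESACC events
  sample-for-sample.
* The plateau rule assumes hold-fill repeats values bit-identically; a
  recording pipeline that re-quantizes positions would need the strict
  plateau setting or a tolerance-based comparison.
* Tracking performance is a global statistic; it does not localize *where*
  in the visual field tracking failed.
* With a single viewing condition or a single group, the corresponding
  model terms are dropped from the main-sequence formula automatically;
  contrasts against the missing level are then, of course, unavailable.
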