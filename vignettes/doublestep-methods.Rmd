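---
title: "Methods: envelope-based correction detection for double-step reaches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope-based correction detection for double-step reaches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublestep)
```

## The measurement problem

A double-step pointing trial asks when, if ever, an in-flight reach begins to
bend toward a displaced target. The hand position signal is a 240 Hz
3-coordinate stream; the displacement is 10° of visual angle left or right
(7.05 cm at the 40 cm viewing distance), scheduled 0 or 200 ms after the
button release that marks reach onset. Three quantities summarise the online
correction:

1. **Correction latency** — the time from the perturbation to the first
   detectable departure of the horizontal trace from the family of
   non-perturbed reaches.
2. **Path linearity / maximum path offset (MPO)** — `L = A/B` with `B` the
   Euclidean start-to-end distance of the path and `A` the largest normal
   distance of any sample to that line; `L = 0` is a perfectly straight path.
   `A` (in cm) is the MPO.
3. **MPO latency** — the time of the MPO sample minus the perturbation time,
   an estimate of when the corrective deviation peaks that does not depend on
   non-perturbed trials at all.

## The envelope detector

For each grouping unit (participant × block by default; a participant-pooled
option exists) the x-traces of cleaned non-perturbed trials are aligned at
reach onset on the common sample grid and averaged per sample; the detection
corridor is mean ± k·SD with k = 1.5. Trials drop out of the average as they
end, so the per-sample support is non-increasing; the envelope is kept up to
the last sample with at least `min_support` (default 10) trials in flight and
its final mean and SD are held constant beyond that point.

A perturbed trial is scanned from its perturbation time. The correction
onset is the first sample at which the trace is outside the corridor *on the
side of the perturbation* and stays outside for `sustain` = 3 consecutive
samples (≈ 12.5 ms at 240 Hz); `sustain = 1` reproduces the bare threshold
rule. Two timing rules matter:

- no onset earlier than `min_delay` = 80 ms after the perturbation is
  accepted — this is the minimum visuomotor delay; a trace that is already
  outside the corridor when the scan opens is assigned exactly 80 ms;
- if no qualifying excursion occurs before touch, *no* latency is recorded
  for the trial (the trial counts as uncorrected, never as zero latency).

Excursions on the side opposite the perturbation are never counted as
corrections (they would be overshoot or noise) but are flagged in the
output, so their frequency can be audited.

### Why the side-consistency and sustain rules

The bare rule "first sample beyond ±1.5 SD after 80 ms" fires on any
excursion, including those away from the displaced target and single-sample
noise spikes. Requiring the crossing to be on the perturbation side halves
the false-positive exposure and matches the question being asked; the
3-sample sustain requirement suppresses isolated spikes without materially
delaying genuine onsets (onsets are reported at the *first* sample of the
sustained run). Both are configurable.

### The intrinsic false-positive floor

A property worth being explicit about: when the perturbed trial is drawn
from the same population as the envelope trials, the probability that its
deviation exceeds the one-sided 1.5 SD boundary at any given sample is the
Gaussian tail mass P(Z > 1.5) ≈ 6.7% — by construction, because the
corridor width is estimated from that same population. Deviations of motor
origin are sustained (a trial biased toward one side stays biased), so the
sustain rule does not remove them, and scanning a window of many samples can
only add crossings. The envelope method therefore has an irreducible
false-positive rate of roughly 7% — in practice somewhat higher, because
trial-to-trial variability has several partly independent components
(endpoint bias, mid-flight deviation, sensor noise) — on trials that contain
no correction at all. The test suite measures this rate on
correction-free perturbation-scheduled trials at default settings (it comes
out near 15% for the shipped generator defaults, against a 5% target that
Gaussian variability cannot meet). Practical consequences: correction
*frequencies* from the envelope method are biased upward by this floor, and
detector specificity should be quoted alongside any frequency table. The MPO
measures are unaffected, which is one reason they are computed.

### Numerical conventions

- Times are seconds on the trial clock; trial-relative quantities are
  milliseconds from reach onset, latencies milliseconds from their stimulus
  (target onset for reach latency, perturbation for correction and MPO
  latency).
- Sample alignment uses the index `round((t − reach_onset) · fs)`; the
  generator places reach onset exactly on the grid, and recorded data
  aligned this way are at most half a sample period off.
- Envelope bounds are exceeded *strictly* (`> k·SD`), so a degenerate
  zero-width corridor (identical noiseless trials) is not escaped by the
  mean trace itself.
- Peak-velocity ties break to the earliest sample; a peak at the first or
  last movement sample flags the profile as degenerate (monotone speed) and
  the trial is reported, not dropped.
- `path_linearity` returns `NA` with a degenerate flag when start and end
  coincide (B = 0); perpendicular distances use the projection identity
  with clamping at 0 to absorb rounding.
- The MAD rule treats a scale at or below `1e-8 · max(1, |median|)` as zero
  spread (values identical up to floating-point jitter) and then flags any
  value off the median beyond that same tolerance; without this, robust
  z-scores explode on deterministic data.

## Filtering

All kinematic measures are computed after two-way (forward–backward,
zero-phase) 4th-order Butterworth low-pass filtering at 20 Hz — the standard
conditioning for motion-tracker kinematics; applied both ways the magnitude
response is effectively 8th order. Plain forward–backward filtering has
start-up transients at the series edges, so the filter operates on an
odd-reflection extension of the series (up to 300 samples per side) and
trims it afterwards; a constant series then passes through unchanged to
below 1e-9. Speed is the central-difference derivative of the filtered
positions, 3D by default with a horizontal-plane option (the literature uses
both conventions).

## The synthetic session generator

The generator is a first-class module: it produces complete sessions with
the statistical structure the analysis assumes, plus ground-truth labels
(true correction onsets, artifact and outlier flags) so detection, cleaning
and summaries can be validated by parameter recovery rather than by
eyeballing.

**What it emulates.** The task geometry (start 40 cm from the screen,
initial target 4.5° above fixation, perturbed targets ±10°), the 240 Hz
sampling, the trial mix (50/25/25 static/left/right, perturbation times
split evenly within direction, randomly interleaved within 80-trial blocks),
uniform 500–1000 ms foreperiods, per-group timing distributions, and
contaminant trials at configurable rates. The primary movement is a
minimum-jerk reach generalised to an asymmetric peak-velocity time: two half
minimum-jerk segments joined at the peak (`reach_profile()`), which keeps
the closed forms — peak speed 1.875·D/T at time `peak_frac·T` — while
letting the deceleration share differ between groups. A corrective
submovement is an *additive* minimum-jerk displacement toward the displaced
target (superposition, the standard submovement-decomposition convention),
with its own duration (200 ms, truncated to the time remaining) and a gain
below 1 to model undershoot. Corrected trials take longer by a per-condition
extension, and the extra time is spent decelerating: the time of peak
velocity is left where the base reach put it, which reproduces the
deceleration-phase prolongation that late corrections show in real reaches.

**Variability model.** Three Gaussian components per trial: an endpoint
bias whose contribution grows with movement progress (SD 0.35 cm ≈ 0.5° of
endpoint scatter), a transient mid-flight deviation shaped `4m(1−m)` that
vanishes at rest and at touch (SD 0.25 cm; signal-dependent motor noise with
feedback homing), and white sensor noise (SD 0.05 cm) low-pass filtered at
10 Hz. The motor components dominate the cross-trial envelope at every phase
of the reach, which keeps the 1.5 SD corridor non-degenerate and puts the
detector in the regime it faces with real recordings.

**Group defaults.** The two shipped groups encode the descriptive structure
of younger vs older adults in this task: reach latency 266 vs 294 ms,
duration 496 vs 532 ms (the task imposes a 550 ms time pressure), peak-time
fraction 0.54 vs 0.50 (≈ 37 ms more deceleration for the older group),
correction probabilities per condition × direction of 100/100/72/66% vs
91/92/59/48%, and higher contamination rates for the older group (9% + 10%
vs 6% + 4%). These are configuration defaults that make the simulated
cohorts structurally realistic; they are not fitted to any dataset.

**What it does not emulate.** No biomechanical arm model, no gaze, no EMG,
no signal-dependent timing of the submovement, no non-Gaussian heavy tails,
no drift or calibration error in the tracker. Passing tests on synthetic
sessions therefore demonstrates that the *pipeline* is correct and
recoverable under its stated assumptions — not that any particular human
dataset satisfies those assumptions.

**Impossible draws.** Non-positive durations are redrawn; correction
latencies that leave less than 60 ms of submovement before touch are redrawn
up to a budget (100), after which the trial falls back to no injected
correction and the fallback is flagged in the ground truth. Under a fixed
seed every session is bit-reproducible.

## Cleaning

Two stages, mirroring practice with real recordings and reported separately:

1. **Error screening** removes trials with a missing touch response, a reach
   onset preceding target onset, more than 3 consecutive missing samples, or
   a zero-length trajectory, itemising the reason per trial. Screening never
   raises.
2. **MAD outlier rejection** flags a trial when any screened measure (by
   default reach latency, duration, peak velocity) has robust z-score
   `|v − median| / (1.4826·MAD) > 3` within its participant × condition ×
   direction cell. The multiplier 3 is the conservative end of the
   conventional 2.5–3 range; cells with fewer than 4 values are left
   untouched with a warning.

## Summaries

Because cleaning removes unequal numbers of trials per participant, cell
statistics are two-stage by default: trials → participant means → cell mean
and SD over participants (a pooled single-stage option exists). The percent
difference `round(|a − b| / ((a + b)/2) × 100)` is provided for group
contrasts, and the participant-level long table is exported for mixed-model
analysis in an external statistics environment — inferential statistics are
deliberately out of scope here.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: closed
forms for minimum-jerk landmarks; brute-force per-sample scans re-deriving
every detection and every MPO argmax (cross-product distance formula vs the
projection identity); template differencing to recover injected onsets; and
generator ground truth for cleaning recovery. Sizes were chosen to give
stable statistics at interactive runtimes: 500 trials for oracle equivalence
and detector specificity, 200 trials for onset recovery, one 480-trial
session for cleaning recovery, 120 trials per cell for correction-frequency
recovery.

Onset-recovery probes deserve a note: they are noise-free
template-plus-correction trials (the generator's validation mode) detected
against an envelope built from low-variability sessions. If probes instead
carry their own motor deviations, the detector's intrinsic early-crossing
rate — the same ≈7–13% floor discussed above, and scale-invariant, since
corridor width and deviation size shrink together — contaminates about one
estimate in eight no matter how small the noise is made. That failure mode
is a property of the method, measured separately by the specificity check;
the recovery check isolates the question it is actually asking: *given* a
correction, how accurately is its onset timed? (Answer, at these settings:
a positive bias of roughly one to four sample periods, rank correlation with
the true onsets above 0.97.)

## Known limitations

- The envelope detector's false-positive floor (above) biases correction
  frequencies upward; compare frequencies only at matched detector settings.
- Whether published analyses take speed in 2D or 3D, or pool envelopes per
  participant rather than per block, is often unstated; both options are
  exposed and default to 3D and participant × block.
- The MPO latency is referenced to perturbation onset (the same clock as
  correction latency); referencing to reach onset would shift it by the
  perturbation time.
- `L = A/B` is dimensionless and the MPO `A` is in cm; both are reported,
  since group contrasts in the literature are sometimes quoted in cm.
- A semicircular path has L = 0.5; the occasional gloss that "L = 1 is a
  circular path" does not follow from the formula, which is what is
  implemented.
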