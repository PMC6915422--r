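---
title: "How ahrswim analyzes a swim session"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How ahrswim analyzes a swim session}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahrswim)
```

## The measurement model

A trunk-worn AHRS (attitude and heading reference system) logs, at a
nominal 100 Hz, the three raw inertial triplets (accelerometer in g,
gyroscope in deg/s, magnetometer in gauss) together with the fused Euler
angles: pitch (nose-up tilt of the trunk), roll (rotation about the
swimmer's long axis) and heading (compass direction). The package analyzes
the Euler angles and the accelerometer; the raw gyroscope and magnetometer
channels are carried through I/O untouched.

The pipeline has four stages, each with its own module:

1. **Lap segmentation** from pitch (`segment_session()`),
2. **Style classification** per lap from accelerometer energy
   (`classify_lap()`),
3. **Stroke counting** per lap from roll or pitch (`count_strokes()`),
4. **Indicators** per lap: lap time, stroke rate, trunk elevation, body
   balance, body rotation (`analyze_session()`).

Angle conventions: pitch is positive nose-up and confined to [-90, 90];
roll is positive toward the swimmer's right in [-180, 180); heading lives
in [0, 360). The synthetic generator and all detectors share these
conventions.

## Lap segmentation

While swimming, trunk pitch stays within roughly ±20°. Wall turns drive
it briefly toward ±90°; a standing stop drives it to -90° and holds.
`detect_events()` therefore marks every maximal excursion of |pitch|
beyond an apex trigger (default 70°, configurable — the excursions are
only "close to" 90°) as one event, and calls it a **stop** when the
governing extremum separation or the out-of-band dwell reaches
`stop_min_s` (default 3 s), else a **turn**. The turn/stop split is by
construction monotone in `stop_min_s`; slow turns by less experienced
swimmers can masquerade as stops, and the remedy is retuning that single
parameter.

Event boundaries are refined by sliding a 0.5 s averaging window one
sample at a time away from the apex until the windowed mean re-enters the
±20° band; at session edges the boundary clips to the signal end, so
warm-up and cool-down fragments stay visible.

Backstroke bucket and cross-over turns may produce no pitch excursion at
all. Those are recovered in two steps: laps whose duration deviates from
the median by more than 3 scaled MADs (median absolute deviation, scaled
by the normal-consistency constant 1.4826) are flagged, and inside each
flagged lap we look for a sustained heading reversal — an accumulated
circular change of at least 150° within 5 s (both invented thresholds,
exposed in `segmentation_params()`). The apex goes to the pitch maximum
nearest the reversal midpoint. Because pitch never leaves the swim band
during such turns, the windowed-mean refinement is degenerate there; the
event extent is taken from the 10% and 90% crossings of the heading ramp
instead. Recovery iterates (re-segmenting after each split) and stops when
no flagged lap contains a reversal. Median-based flagging needs the
merged laps to be a minority — in practice silent turns occur only at
backstroke walls, so this holds for realistic sessions.

Lap times exclude the adjoining events' durations; event durations are
reported separately. Whether a coach prefers wall-to-wall times is a
reporting choice, not a detection one.

## Style classification

Backstroke is the only style swum supine, so the 0.5 Hz low-passed z
accelerometer sits near -1 g instead of +1 g. `is_backstroke()` thresholds
the lap mean at -0.5 g (midway between the two regimes); laps passing the
rule never reach the 3-class model.

For the remaining styles each accelerometer channel is low-passed
(48-order Hamming-windowed FIR, 0.5 Hz cutoff, reflect padding,
group-delay compensated, unit DC gain), converted from g to m/s^2
(x 9.80665), and summarized by its **energy**: the rounded mean absolute
deviation over the lap. Rounding is half-away-from-zero — the definition
only says "round", so the choice is pinned here. Front crawl shows
dominant y-energy (body roll), butterfly exceeds breaststroke in z
(undulation) and x (speed).

Two classifier backends are provided:

* **SVM** (via e1071/libsvm): polynomial kernel with box constraint 1e5
  and degree 1 by default. The degree-1 default makes the kernel affine;
  the degree is exposed for users who want a genuinely polynomial
  boundary.
* **ANN**: a 3-input / 10-hidden / 3-output network trained by full-batch
  gradient descent with momentum (momentum 0.5, learning rate 0.3),
  sigmoid hidden units, softmax output, cross-entropy loss. No stopping
  rule is prescribed by the method description, so training stops when
  the loss fails to improve by 1e-8 for 50 consecutive epochs, capped at
  3000 epochs; weight initialization is seeded, making training
  bit-reproducible.

Both serialize to JSON (support vectors and dual coefficients for the
SVM, reconstructed at load time without the fitted object; plain weight
matrices for the ANN) and reload to identical predictions. A model-free
rule fallback (y-dominance for front crawl, a z-energy threshold for
butterfly vs breaststroke) exists for quick looks; it is deliberately
coarse.

## Stroke counting

**Nonsymmetrical styles** (front crawl, backstroke): every roll peak —
maxima and minima alike — is one arm stroke. The roll is low-passed
(48-order Hamming, 3 Hz), local extrema are found with plateau-midpoint
handling and a 0.25 s minimum separation (invented, configurable;
suppresses noise doubles), and an extremum counts only if (a) it lies
*outside* the band mean ± k·sd of the filtered lap signal and (b)
|roll| ≥ 20°. The per-style k values are fixed constants: 2 (front
crawl), 2.36 (backstroke), 0.74 (breaststroke), 1.34 (butterfly). The
band inequality as printed describes the inside region and does not state
which side gates a peak; we gate on the outside, which is the only
reading under which counts are monotone non-increasing in k. The standard
deviation is the sample sd (ddof = 1) of the filtered signal.

A consequence worth stating plainly: an extremum can only be outside the
band when the signal's peak-to-sd ratio exceeds k. A pure sinusoid peaks
at √2 ≈ 1.41 standard deviations, so for k ≥ √2 (both roll styles) a
strictly sinusoidal roll would yield zero counts. Physically, counting
works because real roll traces spend part of each stroke cycle near
neutral, concentrating variance in bursts; the synthetic generator
reflects this (below).

**Symmetrical styles** (butterfly, breaststroke): one pitch undulation
per stroke cycle, a cycle being the segment between consecutive filtered
pitch minima that pass the k-sigma gate. Each cycle is linearly resampled
to 200 samples; a **mean wave** is the pointwise average of the central
50% (samples 51–150) across cycles; each cycle's central segment is then
compared to the template by dynamic time warping (squared local cost,
symmetric steps, no window, square root of the optimal path cost) and
discarded if the distance exceeds the rejection threshold. The reference
threshold was calibrated on data that is not available, so the default is
self-calibrating — 3 times the median cycle-to-template distance of the
lap itself — with a fixed override available, plus a 1e-6 absolute floor
so that floating-point dust never rejects identical cycles. The template
is built per lap by default; a corpus-level template can be saved and
reloaded as JSON.

The stroke count is the number of surviving extrema (nonsymmetrical) or
surviving cycles (symmetrical). Both counters return the rejected
candidates so that detection accuracy can credit true negatives.

## Indicators

* **Stroke rate**: 60 · count / lap time (strokes/min), lap time
  excluding events. For symmetrical styles the counted unit is the stroke
  cycle.
* **Trunk elevation** (symmetrical only; reported n.a. otherwise):
  per-cycle max-minus-min pitch, mean ± sd per lap.
* **Body balance**: nonsymmetrical, mean ± sd of lap pitch (target:
  near 0); symmetrical, mean ± sd of per-cycle pitch maxima and of
  per-cycle minima.
* **Body rotation**: the mirror image on roll — symmetrical, lap mean ±
  sd (target near 0); nonsymmetrical, per-side statistics of stroke-peak
  roll (unequal sides flag stroke asymmetry).

Reported Min/Max are defined numerically; session aggregates are pure
functions of the lap table and are recomputable from it. All sd values
use the sample convention (ddof = 1).

**Detection accuracy** is (TP + TN) / (TP + FP + TN + FN). The prose
definition of FP/TN in the source method is not operational, so matching
is pinned down as: detections pair one-to-one with true stroke times by
nearest neighbor within 0.3 s (configurable); unmatched detections are
FP, unmatched truths FN, and rejected candidates count as TN when not
within tolerance of any truth (rejected candidates adjacent to an
already-matched truth are ignored).

## The synthetic generator

No recordings ship with the package, so `generate_session()` produces
seeded sessions with aligned ground truth. What it emulates:

* **Roll styles**: alternating-sign raised-cosine rotation bursts, one
  per stroke, occupying 35% of the stroke cycle (peak-to-sd ratio
  1/√(0.375·0.35) ≈ 2.76, chosen analytically to clear the largest gate
  k = 2.36 with margin), default amplitudes 45° (front crawl) and 40°
  (backstroke), rates 50 and 45 strokes/min.
* **Pitch styles**: sinusoidal undulation, one cycle per stroke
  (amplitudes 35°/30°, rates 40/30 cycles/min, baseline pitch -5°), with
  an optional turn-approach artifact: an extra same-amplitude but
  sharpened (cos^5) cycle appended to the lap, which is not a true stroke
  and must be rejected by the gating/DTW stages.
* **Turns**: raised-cosine pitch pulses to ±88° (1.6 s default) with a
  smooth 180° heading ramp; bucket/cross-over variants mute the pulse to
  12°, below the detection band. **Stops** hold pitch near -88° for 5 s.
* **Accelerometers**: z sits at -1 g for backstroke and +1 g otherwise;
  per-axis 0.2 Hz oscillations are scaled so the rounded energy features
  land near (2, 6, 2) m/s^2 for front crawl, (4, 2, 6) for butterfly and
  (1.5, 1, 2) for breaststroke, jittered ±15% per lap — reproducing the
  qualitative cluster geometry of the three prone styles.
* **Noise**: additive Gaussian, defaults 1.5° on angles and 0.03 g on
  accelerations. The source material reports no noise figures; these are
  plausible consumer-AHRS values chosen once and documented here, not
  measured constants.
* Gyroscope channels are derivatives of the clean angles; magnetometer
  channels follow the clean heading. Both get small additive noise and
  exist for I/O fidelity only.

What it does **not** emulate — and therefore what passing tests do not
show about real data: waveform variability between swimmers and within a
lap (fatigue, breathing), stroke-rate drift, glide-phase kicks,
push-off dynamics, sensor drift or dropout, and the overlap between
butterfly and breaststroke energy clusters seen in real recordings. The
synthetic feature clusters are separable by construction, so the ~100%
classifier accuracy on generated corpora is an upper bound, not an
estimate of field performance; on real recordings the wearable-swimming
literature reports around 89–90% for the 3-class problem.

## Numerical choices and degenerate inputs

* FIR coefficients are normalized to exact unit DC gain; edges are
  reflect-padded; the group delay (order/2 samples) is compensated.
* A constant series has zero sd: the band mask is all-false (no
  candidates), and the scaled MAD of an all-equal vector is 0, making
  every non-median lap time an "outlier" — recovery then simply finds no
  heading reversal and leaves such laps alone.
* Local extrema on plateaus are reported at the plateau midpoint.
* Cycles are resampled on a time-normalized grid by linear
  interpolation.
* Sessions must be uniformly sampled within 10% of the nominal rate
  (the FIR designs assume fixed fs); `resample_session()` is the explicit
  repair, never applied automatically.
* Lap sample spans are half-open; lap indexing is 1-based.

## Problem sizes used in validation

The bundled tests and the acceptance script run entirely on generated
data at desk scale: 50 mixed-style sessions (six or eight laps each, all
turn variants and stops, default noise) for segmentation; 50 laps per
style for the backstroke rule and for each stroke-counting corpus (the
butterfly corpus includes turn-approach artifacts in every third lap);
and ≥1000 randomized small instances for each brute-force oracle
(scaled MAD, band mask, channel energy, DTW vs exhaustive path
enumeration, accuracy tabulation vs naive re-tabulation).
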