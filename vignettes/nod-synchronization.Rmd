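---
title: "Nod-based synchronization of eye tracking and motion capture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nod-based synchronization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodsync)
```

## The synchronization problem

A motion-capture system and a head-mounted eye tracker record on
independent clocks. Without a shared trigger, two unknowns corrupt joint
analyses: the *offset* between recording starts (typically around a second
when devices are started by hand, one after the other), and *drift*, the
slow divergence of the two clocks over the session. `nodsync` estimates
both from a deliberate behavioral event — a single quick head nod performed
while fixating a target with eyes open — that leaves a sharp synchronous
dip in the vertical head-marker trajectory and in the vertical pupil image
coordinate.

The method assumes:

* the nod is one continuous down–up movement (no pause at the bottom), so
  each channel has a single well-defined displacement minimum with a
  velocity zero-crossing at its apex;
* the eyes stay open through the nod, so the pupil channel has data where
  it matters (a blink there is the dominant failure mode, handled below);
* both devices sample uniformly at a known nominal rate; alignment is
  expressed in seconds, so the rates need not match (200 Hz and 50 Hz is
  the supported reference pairing; an integer rate ratio minimizes rounding
  when trimming).

## The detection chain

Each channel runs through the same five steps, in a fixed order
(`prepare_channel()` then `detect_sync_point()`):

1. **Linear gap-filling.** Missing samples — blinks in the pupil trace,
   occlusions in the marker trace — are replaced by linear interpolation
   between the nearest valid neighbours, irrespective of gap length; the
   samples themselves are never used for anything but continuity, so no
   maximum-gap threshold is needed. Leading/trailing gaps have only one
   valid neighbour and hold its value (linear interpolation is undefined
   there, and real gaps of interest are interior). The interpolated frames
   are remembered for the confidence check.
2. **Smoothed differentiation.** Central differences scaled by the sampling
   rate (one-sided at the edges, preserving length), then a second-order
   Butterworth low-pass run forward and backward. The forward–backward pass
   makes the net filter zero-phase: a causal filter would delay the dip and
   bias every sync point late by a rate-dependent amount, silently
   corrupting the *offset* (which mixes two rates). Differentiation also
   removes participant-height baselines and slow pre-nod posture drifts.
3. **Prefix zeroing.** The first 1.5 s of the mocap velocity and 1.0 s of
   the pupil velocity are set to zero. The devices are started
   consecutively — mocap first, hence its longer window — and the moments
   before the participant settles on the target can contain movement
   artefacts that would otherwise offer spurious minima to the peak-picker.
4. **z-scoring** over the whole processed channel, including the zeroed
   prefix. Standardization makes the threshold portable across
   participants who nod with different vigour. Including the prefix in the
   statistics follows the processing order above; its effect is a slightly
   smaller standard deviation, i.e. marginally deeper z-values.
5. **Peak-picking and zero-crossing.** Scanning forward in time, the first
   *strict* local minimum below the threshold (default −2 z-units) marks
   the nod's downward flank. The apex of the nod is where velocity changes
   sign, and since a sampled velocity is essentially never exactly zero,
   the sync point is the frame *n* before the first crossing
   `v[n] < 0 ≤ v[n+1]`. For the end nod the scan runs backwards from the
   end of the recording to the *last* qualifying minimum, and the same
   forward crossing rule applies from there; the sync point stays
   expressed relative to the recording start, so no trimming is implied.

Ties on flat minima resolve to the first frame of the plateau — an
arbitrary but deterministic choice; with real (noisy, floating-point)
velocities, exact plateaus essentially never occur.

## Alignment and drift

With sync points `t_m` (mocap) and `t_e` (eye), the offset is
`Δ = t_m − t_e`, positive when the mocap system started earlier (the
supported protocol). Trimming removes `round(Δ · f_mocap)` whole frames
from the start of the mocap channels — whole-frame trimming is the only
lossless option without resampling — and reports the sub-frame remainder
(`residual_s`, at most half a mocap frame). A negative offset trims the
gaze stream instead; the protocol never produces it, but symmetry is the
natural completion.

For drift, the start and end nods give per-stream durations measured on
each device's own clock; `difference_s = eye − mocap`. Scattered
positive/negative differences of a few milliseconds reflect frame
quantization (each of the four sync points is quantized to its stream's
frame grid); a consistent sign across long recordings indicates a real
rate mismatch. `summarize_drift()` aggregates sessions by the mean of
*absolute* differences — signs flip with rounding, so the magnitude is the
informative per-participant statistic — plus range and count.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold_z` | −2 | z-units | deep enough that noise rarely qualifies, shallow enough for gentle nods; exposed because nod vigour varies by population |
| `cutoff_hz` | 10 | Hz | a nod lasts ~0.3–0.5 s, so its velocity content lies below ~5 Hz; sensor noise lies above; 10 Hz keeps the dip sharp while suppressing noise at 120–200 Hz (mocap) and 50 Hz (pupil) alike |
| filter `order` | 2 | — | standard smoothing-differentiation practice; higher orders buy little at these cutoffs and ring more |
| `prefix_zero_mocap_s` | 1.5 | s | mocap starts first; covers operator reaction time plus settling |
| `prefix_zero_pupil_s` | 1.0 | s | eye tracker starts ~1 s later; same purpose, shorter window |
| `dip_sign` | +1 | — | +1 when the nod is a minimum in the raw channel (z-up mocap; image-down-positive pupil y); −1 flips inverted axes |
| `sd_type` | "sample" | — | z-scoring divides by the n−1 standard deviation, the convention of the common statistics toolboxes; since the threshold is expressed in these units the convention is pinned and configurable |
| `blink_overlap_max` | 0.5 | fraction | a sync point whose flank support is more than half interpolated rests mostly on reconstructed data |
| `prominence_min` | 5 | robust SDs | post-hoc nod check, see below |

## The blink failure mode and the post-hoc nod check

If the participant blinks *through* the nod, gap-filling bridges the dip
with a straight line and the true event is simply gone. Crucially, the
detector cannot then fail with "no nod found": z-scoring rescales whatever
remains to unit variance, and several hundred frames of smoothed noise
reliably contain local minima below −2. The naive outcome is a confident
sync point at a random noise excursion.

Two complementary guards catch this:

* **Flank overlap** — if more than `blink_overlap_max` of the frames
  supporting the detected minimum (from the last non-negative velocity
  frame before it to the frame after the zero-crossing) were interpolated,
  the point is flagged; this catches blinks that clip part of the nod.
* **Prominence** — the detected minimum must exceed `prominence_min` times
  the channel's robust noise scale (median absolute deviation). A real nod
  stands 15–50 robust SDs out of the noise floor; a spurious noise minimum
  sits at 3–4. The default of 5 separates the two regimes with a wide
  margin on both sides. This check is this package's own addition — a
  post-hoc verification that what was detected is nod-like — and can be
  disabled (`prominence_min = 0`).

Flagged points are returned (with `low_confidence = TRUE`) rather than
suppressed, so interactive users can inspect them; the batch CLI treats a
flag as failure.

## What the simulator emulates — and what it does not

`simulate_session()` generates the two streams on a shared world clock:
the mocap system starts at *t* = 0, the eye tracker `true_offset_s` later
(default 1.0 s); the nod is a raised-cosine dip (default 80 mm deep over
0.4 s for the marker, 60 px for the pupil) centred at a common world time;
per-frame additive Gaussian noise (1 mm / 0.5 px defaults), optional
blinks, and an optional eye-clock rate error in ppm complete the model.
Defaults describe a brisk single nod in a standing-participant protocol;
the dip shape is an analytic stand-in for real nod kinematics, chosen
because it is smooth, unimodal and differentiable with a well-defined
apex — the properties the detector relies on.

The simulator deliberately omits: autocorrelated sensor noise, pupil-size
and corneal-reflection artefacts, partial marker occlusions with
reconstruction error, sampling jitter (only constant-rate skew is
modelled), multi-nod warm-up sequences, and any realistic distribution of
nod depth/duration (none is available). Passing recovery tests on this
model therefore demonstrates the pipeline's arithmetic and its robustness
to white noise, frame quantization and blinks — not performance on every
real-world artefact; with real recordings, the position-minimum oracle
(`ground_truth_minimum()`) and the low-confidence flags are the intended
verification tools.

## Numerical choices and degenerate inputs

* The zero-crossing comparison uses `v[n] < 0` and `v[n+1] ≥ 0`; the `≥`
  closes the measure-zero case of an exact zero sample.
* Velocity of a constant channel is identically zero and cannot be
  z-scored; this raises a classed error (`nodsync_degenerate_series_error`)
  rather than producing NaNs.
* The smoothing filter needs a minimum series length (a few filter lengths
  for the forward–backward pass); shorter inputs raise
  `nodsync_filter_error`. The cutoff must lie below the Nyquist rate of
  the channel it is applied to.
* Text round-trips write six decimals; values re-read from disk are exact
  fixed points of a second write–read cycle.
* Trimming rounds to the nearest frame of the trimmed stream; the residual
  is bounded by half that stream's frame period and is reported, not
  discarded.

## Problem sizes in the test suite

The bundled tests simulate 8-second sessions at 200/50 Hz for recovery
sweeps (50 sessions noisy, 50 noise-free) and one 66-second session for the
skew scenario — sizes chosen so a full run finishes in seconds while every
session still contains hundreds of frames per stream on both sides of the
nod. The acceptance script (`scripts/acceptance.R`) uses the same
50-session design and reports the maximum absolute offset error in
milliseconds; at the default noise levels it lands near 21 ms, inside the
25 ms bound implied by one frame of uncertainty per device (5 ms + 20 ms).

## Known limitations

* Accuracy is bounded by the slower device: one eye-tracker frame (20 ms at
  50 Hz) of uncertainty is irreducible without a faster tracker.
* Only the start/end two-point comparison is offered for drift; fitting a
  clock model (rate + offset) would need more anchor events or hardware
  timestamps, and jitter within a stream is invisible to this method.
* The detector assumes a single nod per scan direction; deliberate
  multi-nod protocols would require windowed searches
  (`ground_truth_minimum()` accepts a window; the velocity detector scans
  whole streams).
* The mocap TSV reader supports a header-plus-triplets text dialect;
  binary formats (e.g. C3D) must be exported to text first.
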