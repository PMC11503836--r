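---
title: "Tracking livestock through occlusion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking livestock through occlusion: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdtrack)
```

This vignette explains the models inside `herdtrack`, the assumptions
they make, the parameters that matter and why their defaults are what
they are, and the design choices taken where the design was genuinely
open. It states no empirical result beyond what the package's test suite
and `scripts/acceptance.R` compute.

## The tracking problem

A barn camera watches a pen of cattle at 25 frames per second. A
detector proposes, per frame, a set of axis-aligned boxes with a
confidence score and a behavior class from the seven-class ethogram
(feeding, drinking, standing, lying, walking, climbing, fighting); an
optional re-identification network attaches a unit-norm appearance
embedding to each box. Tracking-by-detection turns these per-frame
proposals into persistent identities. The difficulties are the usual
ones of dense animal pens: animals occlude each other for seconds at a
time, confidence collapses under partial occlusion, and clutter produces
spurious boxes.

## Motion model

Each track carries a linear-Gaussian constant-velocity filter over the
8-vector (cx, cy, w, h, vcx, vcy, vw, vh) — box center, size and their
per-frame velocities — observed through z = (cx, cy, w, h). Process and
measurement noise standard deviations are proportional to the current
box size (weights 1/20 for position, 1/160 for velocity), so a large
animal near the camera tolerates proportionally more jitter than a
distant one. The covariance update uses the symmetric form
P ← (I − K H) P. Assumptions: per-frame motion is approximately linear
(true at 25 fps for walking cattle), and detector noise is roughly
Gaussian with size-proportional scale.

Boxes are stored as (left, top, width, height) with a top-left origin
throughout; every conversion goes through `box_center()` /
`box_from_center()`, and degenerate boxes are rejected at construction
rather than propagated as NaN.

## Confidence-tiered association

Detections are partitioned at θ~high~ = 0.5 and θ~med~ = 0.3: high-tier
detections ([θ~high~, 1]) drive round 1, medium-tier ones join round 2,
and anything below θ~med~ is discarded outright — in a cluttered pen,
low-confidence boxes are more often noise than animal. Both thresholds
are configuration keys.

Round 1 matches high-tier detections against all non-deleted tracks
(lost tracks included, so re-identification can happen) with a fused
cost. The motion cost is 1 − DIoU, where
DIoU = IoU − ρ²(centers)/C² adds a center-distance penalty normalised
by the squared diagonal of the smallest enclosing rectangle: unlike
plain IoU it still ranks candidates when overlap is marginal, preferring
the center-closest one. The appearance cost is the cosine distance
between the detection embedding and the track's exponentially smoothed
feature (weight 0.9, frozen while lost). Fusion is the gated minimum
used by the BoT-SORT family: the appearance cost is halved and used only
where it is confident (< 0.25) and the candidate is spatially plausible
(motion cost < 0.5); entries with motion cost above a hard gate are
forbidden. A weighted-sum fusion is available by configuration. Round 2
matches the leftovers (medium tier plus unmatched high tier, switchable
to unmatched-high-only for a literal two-round reading) with the motion
cost alone, at a stricter acceptance threshold (0.5 versus 0.8).

Assignment is solved exactly by a Jonker–Volgenant shortest augmenting
path solver (compiled); the tests verify optimality against exhaustive
permutation enumeration. Unmatched high-tier detections with confidence
at least 0.6 start new tracks; tracks unmatched for more than
`max_lost = 30` frames (1.2 s at 25 fps) are deleted. An activated and a
lost track overlapping at IoU ≥ 0.85 are treated as duplicates of one
target and the younger is dropped — without this, a duplicate pair can
alternate over one animal and inflate identity switches.

## Occlusion recovery: virtual observations

While a track is lost it coasts on predictions alone and its error
grows. On re-acquisition, the package fits one interpolating cubic
spline per measurement coordinate through observations that bracket the
gap — pre-loss observations plus the re-detection — evaluates the
splines at the missed frames to synthesise *virtual observations*, and
replays those through the filter from the posterior at the last real
update.

Three numerical choices matter here:

- **Boundary conditions.** An interpolating cubic spline needs two
  conditions beyond interpolation and C² continuity. The default is
  not-a-knot, which reproduces polynomials up to degree 3 exactly
  (verified to 1e−8 in the tests); natural boundaries are available.
  At least 4 support points are required; with fewer, the tracker falls
  back to linear interpolation across the gap.
- **Support selection.** The pre-loss support points are spread across
  the track's recent-observation window (up to 15 frames) rather than
  taken from consecutive frames. An interpolating cubic through knots
  one frame apart amplifies detector jitter severely in the middle of a
  long gap — in simulation, 1 px of jitter became several px of mid-gap
  excursion — while a longer knot baseline keeps the interpolant's
  derivatives conditioned.
- **Covariance handling.** Virtual observations are interpolations, not
  measurements; replaying them as if they carried fresh information
  would shrink the covariance and cause the filter to partially ignore
  the next *real* detections. The tracker therefore adopts the replayed
  mean (position and velocity consistent with the virtual trajectory)
  but keeps the coasted covariance. In simulation on quadratic paths
  this combination dominates both plain replay and predict-only
  coasting, with and without detection noise. `replay_gap()` itself
  returns the standard filter posterior, so the primitive remains
  testable against closed-form oracles.

Virtual frames are recorded in the track table flagged `virtual = TRUE`
with the class label of the nearest real observation. They are excluded
from written MOT output, evaluation and behavior budgets by default: the
tracker's deliverable is what it observed, and gap time is reported as
gap. Re-update applies on any re-match of a track with a non-empty gap,
whichever matching round produced it, and sizes interpolated below 1 px
are floored (boxes are physical). Whether to defer re-update until
several post-redetection frames accumulate was an open choice; it is
applied at the first re-match, where the correction is available
earliest.

## Evaluation metrics

The evaluator implements the standard suite. CLEAR matching runs per
frame at IoU ≥ 0.5 with match persistence (an established pair is kept
while it stays above threshold); MOTA = 1 − (FN + FP + IDS)/GT; an
identity switch is counted when a ground-truth identity's matched
prediction id differs from its most recent previous match. MOTP is
reported as the mean IoU of matched pairs in percent — a similarity
scale, consistent with how tracking papers in this area report it —
rather than a pixel distance. MT/ML use the 80%/20% MOTChallenge
cutoffs. IDF1 pairs identities globally to maximise overlap-matched
detections. HOTA follows the published definition — detection accuracy
and association accuracy combined as a geometric mean and averaged over
localisation thresholds α = 0.05…0.95 — and is cross-checked in the
tests against an independent Python implementation at 0.1 pp tolerance.
Matching is class-agnostic by default (a `class_aware` flag restricts
matches to equal behavior classes). Multi-sequence reports pool counts
and recompute ratio metrics from the pooled counts.

## The synthetic scene generator

Real barn video is rarely shareable, so every test runs on a seeded
simulator that emulates the factors that make barn tracking hard:
sparse versus dense herds, scheduled occlusion events (duration 5–15
frames by default) plus geometry-induced dropout when one animal covers
another beyond a threshold (depth ordered by identity), partial
occlusion degrading confidence into the medium tier, uniform clutter
false positives mostly below θ~med~, random misses, Gaussian box jitter,
and per-identity appearance embeddings with cosine self-similarity
around 0.9. Behavior labels follow a seven-state Markov chain with a
dwell-time minimum (default 1 s); stationary behaviors pin the animal in
place while walking, climbing and fighting move it under random
accelerations capped at 4 px/frame, with reflection at the arena walls.
Three presets encode the main regimes: `sparse_day` (8 animals, light
occlusion), `dense_occluded` (25 animals, heavy pairwise overlap,
frequent events) and `night_low_conf` (confidence mass shifted toward
the medium tier).

What the simulator does *not* emulate: camera motion (the tracker's CMC
hook is exercised with synthetic affine transforms instead), detector
box drift correlated over time, near-duplicate detections of one animal,
and appearance drift with pose or lighting. Passing tests on simulated
scenes therefore demonstrate the pipeline's correctness and its
qualitative behavior under occlusion and clutter, not field performance
on any particular farm. In particular, directional comparisons between
cost functions (DIoU versus IoU) are sensitive to exactly the real-video
properties the simulator omits; on synthetic scenes the two are close to
equivalent, with DIoU slightly stricter at equal thresholds because
DIoU ≤ IoU pointwise.

## Problem sizes in the tests

The test suite and acceptance script size their simulations for a
desk-scale run: the identity end-to-end check uses 10 animals over 500
noise-free frames; the reference-evaluator cross-check uses 10 sparse
scenes of 60–80 frames; the ablation experiments use 20 seeded
dense-occluded scenes of 240 frames (about 10 s of video each) with the
full default configuration, comparing means across seeds. Oracle checks
(rasterized IoU, exhaustive assignment enumeration, closed-form Kalman
limits, polynomial spline reproduction) run at the sizes stated in the
tests.

## Known limitations

- The constant-velocity model has no notion of interaction; two animals
  walking through each other's paths can still swap under any cost.
- Re-update repairs the state but cannot repair a wrong re-match; with
  long gaps and drifted predictions, appearance is the only rescue, and
  it is gated by spatial plausibility.
- The behavior analytics trust the detector's class labels after
  majority-vote smoothing (window 9 frames, ties keep the previous
  label); systematic classifier confusion (e.g. feeding versus standing
  head-down) passes straight through.
- Thresholds are calibrated for the 25 fps, 1280×720 setting the
  defaults describe; other frame rates scale the meaning of `max_lost`
  and the velocity noise weights.
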