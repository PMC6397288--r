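---
title: "Detector fusion and temporal accumulation for aerial thermal wildlife surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detector fusion and temporal accumulation for aerial thermal wildlife surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatfuse)
```

## The problem

Cryptic arboreal mammals such as koalas are hard to count. Ground
observers detect well under all animals present, and manual frame-by-frame
review of aerial thermal video is slow and error-prone. A practical
alternative is to fly a small RPAS with a thermal camera at low altitude
over the canopy at first light, when endothermic animals stand out
against the cool vegetation, and to detect their compact warm signatures
automatically. Single-frame detectors, however, miss animals (occlusion,
noise) and fire on transient clutter. `heatfuse` implements the pipeline
that addresses both failure modes by *fusing several detectors* and
*accumulating their evidence over time in a common, motion-compensated
coordinate frame*, then reduces the surviving detections to one event per
animal and scores whole surveys against ground-truthed animal positions.

## The model

**Heat maps.** Each detector emits per-frame bounding boxes with
confidences in $[0,1]$. After discarding detections with confidence below
0.05 (a deliberately permissive cut; suppression of clutter is the
accumulator's job, not the filter's), each detector's boxes are
rasterized into a binary heat map the size of the frame: a pixel is 1 iff
it lies inside at least one box. The per-detector maps are averaged
pixel-wise into the frame map $I(t)$; with two detectors its values are
0, ½ or 1 — the fraction of detectors that report each pixel. A union
(max) combination is available as an option, but averaging is the
default.

**Registration.** The camera moves (~0.9 m between frames at 8 m/s and
9 Hz), so consecutive frames are aligned before any temporal pooling.
Corners are detected on percentile contrast-stretched copies of the
16-bit frames (Harris response, 3×3 non-maximum suppression, quadratic
subpixel refinement, a budget of 500 keypoints per frame), described with
256-bit binary intensity-comparison descriptors on a smoothed patch,
matched by mutual-nearest Hamming distance, and a planar homography is
fitted with RANSAC (3 px reprojection gate, adaptive iteration count) and
refined on the inliers by normalized DLT. At least 4 point matches are
required; with fewer, or if the robust fit fails, registration is
*absent* for that frame pair.

**Accumulation.** The evidence map follows the registered exponential
moving average
$$A(t) = \frac{I(t)}{N} + \frac{N-1}{N}\,A(t-1),$$
where $A(t-1)$ is first warped into frame-$t$ coordinates through the
inter-frame homography, and $N$ controls the temporal memory. When
registration fails the accumulator resets, $A(t) = I(t)$; the same
initialization is used at $t=0$. Under a constant input $v$ the
recurrence converges as $A(k) = v\,(1 - ((N-1)/N)^k)$, which the test
suite verifies to $10^{-12}$ against direct iteration. Because each
update is a convex combination of values in $[0,1]$ (and bilinear
interpolation cannot overshoot), $A$ stays in $[0,1]$ everywhere.

**Candidates.** Pixels with $A \ge 0.05$ are foreground (the boundary is
retained); 8-connected components whose bounding box is between 3 and
30 px *inclusive* in both width and height become candidate signatures —
the plausible size range of a koala-scale animal at ~60 m altitude.
8-connectivity is used so the diagonal warm pixels of one animal are not
split; the gate applies to the bounding-box extent, not the pixel count.

**Tracking.** Candidates are associated frame-to-frame with a greedy
algorithm: active tracks are motion-compensated through the current
homography, all (track, candidate) pairs are sorted by centre distance,
and pairs are accepted greedily within a 15 px gate, ties breaking to the
lower track id then the lower candidate id. Unmatched candidates spawn
tracks; tracks close after 5 consecutive missed frames; tracks of fewer
than 2 members are discarded. One persistent animal therefore yields one
event. Motion compensation matters: without it the camera's own ~5–11 px
per-frame displacement would exceed any reasonable gate.

**Georeferencing and classification.** Each event member is projected to
the ground with a nadir pinhole model — offset from the principal point,
scaled by the ground sampling distance (GSD), rotated by heading, added
to the aircraft position — and the event takes the median member ground
position. Events are then classified by a rule cascade that mirrors
manual review practice: vehicle- and person-template sizes and speeds
first; then kangaroo-scale (open terrain and either rapid motion
> 4 px/frame or width > 20 px); then candidate (both dimensions in
3–30 px and camera-compensated motion ≤ 1 px/frame); everything else is
`other`. Candidate events are matched one-to-one to ground-surveyed
animal positions greedily by distance within 15 m; unmatched candidates
are relabelled `other`.

**Evaluation.** A survey reduces to counts: $K_{obs}$ animals present,
$K_{detected}$ matched, and $K_{false}$ `other` signatures. The framework
reports the probability of detection $P_d = K_{detected}/K_{obs}$, the
precision rate $PR = K_{detected}/(K_{obs}+K_{false})$, pooled variants
over survey sets, RMSE and MAE of the per-survey count error, and the
composition of false positives by class. Report percentages round half
away from zero, matching the convention of printed survey tables.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| confidence filter | 0.05 | — | permissive; boundary kept (strictly-below excluded) |
| heat-map threshold | 0.05 | — | same value applied to the accumulated map |
| accumulator `N` | 9 | frames | one second of memory at 9 Hz |
| candidate size gate | [3, 30] | px | koala-scale signatures at ~60 m, inclusive bounds |
| tracker gate | 15 | px | about half the maximum signature width |
| missed budget | 5 | frames | roughly half a second at 9 Hz |
| minimum event length | 2 | frames | suppresses single-frame flicker |
| matching radius | 15 | m | order of canopy positional error |
| minimal / rapid motion | 1 / 4 | px/frame | camera-compensated; qualitative field criteria made explicit |
| kangaroo / car width | > 20 / ≥ 35 | px | distractor size bands at the default GSD |

The GSD is a required input for georeferencing: the camera's focal length
may be known (13 mm is typical for this class of sensor) but the detector
pitch usually is not, so no default is assumed; `camera_model()` accepts
either the GSD directly or focal length, pixel pitch and altitude.

Where a published description of this workflow leaves a choice open, this
package decides it explicitly: the 0.05 cut is applied both per detector
and to the accumulated map (each independently configurable); $I(t)$ is
the *average* of the binary detector maps, not a re-binarized union
(union is an option); component-size bounds are read inclusively;
overlapping detections need no pre-merging because rasterization is
idempotent on overlaps.

## The synthetic survey generator

Real surveys of radio-collared animals cannot be redistributed, and the
trained neural detectors are out of scope, so the package ships a
simulator that emulates everything downstream code consumes: 16-bit
frames of correlated canopy texture (blurred Gaussian noise) with a
disjoint smoother open-terrain strip; warm, flat-topped animal blobs of
3–30 px placed in the canopy; wider (> 20 px), fast-moving kangaroo-like
distractors plus optional car- and human-scale objects on open ground; a
nadir camera flying a lawnmower pattern at 8 m/s and 9 Hz at 60 m with
exact per-frame homographies (translation plus optional slow heading
wobble); per-frame Bernoulli canopy occlusion; telemetry with lat/lon on
a local tangent plane; and two mock detectors with configurable miss
rate, Poisson false-positive rate, box jitter and Beta-distributed
confidences. Identical configuration and seed give bit-identical output,
down to the serialized fixture.

What the simulator does *not* emulate: radiometric physics, weather,
motion blur, rolling shutter, terrain relief (the projection assumes flat
ground at nadir), detector confidence correlated with appearance, and
spatially correlated detector failures. Passing tests on synthetic
surveys therefore validate the *mechanics* of the pipeline — fusion,
registration, accumulation, gating, tracking, georeferencing, scoring —
not field detection performance; field-scale probability-of-detection
values are an empirical property of real imagery and trained detectors.
The thermal contrast default (12 000 counts over a 20 000-count canopy
with 1 500-count texture) is a free parameter chosen so a plain intensity
threshold separates animals on noise-free scenes; it is not a claim about
real radiometry.

## Numerical choices

* Pixels are 0-based, half-open, x right / y down; boxes are
  $[x_0,x_1)\times[y_0,y_1)$ and are clipped to the frame, never
  rejected.
* Warping uses inverse mapping with bilinear interpolation; pixels
  mapping outside the source contribute 0, so evidence decays at the
  leading frame edge rather than being extrapolated.
* Homographies are normalized to unit bottom-right entry; singular
  matrices raise an error that callers treat as registration failure.
* Component labeling is union-find over the foreground scan;
  the test suite checks it against an independent flood-fill oracle
  exhaustively on all 512 3×3 masks and on random 12×12 masks.
* Greedy association is deterministic: distance, then track id, then
  candidate order. Greedy is not globally optimal in general; the suite
  verifies it against a brute-force optimal-assignment oracle on
  well-separated instances (where the two coincide) and against an
  independent naive greedy oracle elsewhere.
* All randomness (simulator, mock detectors, RANSAC sampling) flows
  from explicit seeds through a state-preserving scoped RNG, so library
  calls never perturb a caller's random stream.

## Reproduction problem sizes

The bundled tests and the acceptance script run the pipeline at desk
scale, the package's own choice of reproduction size: 192×256 px frames
at 0.18 m/px (≈ 4.9 px inter-frame motion), single-transect surveys of
55–103 frames over a 46 m × 100–125 m world with 4–12 animals, and a
20-replicate study (tests) or 10-replicate study (acceptance script) with
two independent mock detectors at a 30 % per-frame miss rate. The
evaluation framework is additionally exercised on a bundled table of
eleven real koala surveys (two sites, North and South, near Petrie,
Queensland) with ground-survey counts and both automated and manual
detection counts; the package reproduces that table's per-survey and
pooled percentages, its RMSE/MAE comparison over the seven-survey subset
(North 3–6, South 3–5) that is consistent with all four published error
values, and its false-positive composition. For the composition the
denominator is the sum of the class counts (21 + 9 + 3 + 40 = 73), which
is what the published shares 29/12/4/55 % are consistent with, rather
than the table's printed total of 64.

## Known limitations

* Consecutive-frame registration accumulates drift over long sequences;
  there is no global adjustment or mosaicking. The accumulator's finite
  memory makes this harmless for detection, but tracks spanning hundreds
  of frames would degrade.
* The nadir flat-ground projection ignores gimbal attitude error and
  terrain relief; georeferencing error grows with both.
* A fast-moving warm object smears in the accumulated map and can exceed
  the size gate, fragmenting its track; this is by design (the gate
  targets sedentary canopy animals) but means distractor *counts* are
  less reliable than distractor *suppression*.
* `K_detected` is capped at `K_obs` by one-to-one matching against
  collared animals, so detections of uncollared animals deflate the
  precision rate — a conservative convention inherited from the survey
  design that motivated the evaluation framework.
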