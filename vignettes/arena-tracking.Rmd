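---
title: "Tracking multiple unmarked bees on a flat arena: methods and design"
author: "beetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking multiple unmarked bees on a flat arena: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetrack)
```

## The problem

Honeybees observed on a flat arena under red light are dark, low-contrast,
visually indistinguishable blobs that rest for long periods, touch, overlap
and wait on one another. Generic multi-animal trackers built around
constant-velocity motion and background adaptation lose exactly these
behaviors: a resting bee fades into an adaptive background, and contacts
scramble identities. `beetrack` implements a tracking pipeline whose
assumptions match this setting, a simulator that generates arena movies with
exact ground truth, and the metrics needed to quantify tracking quality.

This vignette documents the model, its assumptions, the tunable parameters,
the numerical choices, and what the synthetic validation does and does not
demonstrate.

## Segmentation model

**Assumptions.** Stable lighting; a static, bright arena; animals strictly
darker than every background pixel they ever cover; a camera fixed over the
arena.

**Background.** The model image is the per-pixel maximum gray value over all
frames (`buildBackground()`). Under the assumptions above this converges to
the true empty-arena image as soon as every pixel has been animal-free in at
least one frame; a pre-recorded empty-arena image can be supplied instead and
is used verbatim. There is deliberately **no** rolling update: adaptation is
what makes resting animals disappear in other trackers.

**Binarization.** A pixel is foreground iff
`background − frame ≥ threshold`, with the difference clamped at zero so that
pixels *brighter* than the background (glints) are never foreground. The
comparison is `≥`, fixed for reproducibility. The default threshold of 43
gray levels is the reference value for the kind of footage the package
targets; on clean synthetic footage tracking quality is flat over a wide
threshold band, which `thresholdSweep()` makes easy to verify for any given
movie.

**Components.** Foreground pixels are grouped by 8-connectivity (thin bee
bodies touch diagonally often; 4-connectivity is available in the config).
Labeling is a two-pass union-find pass implemented in C++ and cross-checked
in the test suite against a pure-R flood-fill oracle. Region features are the
pixel count, the centroid (mean member coordinate; x = column, y = row,
0-based), the bounding box and the moment-ellipse axes from second-order
central moments. Regions touching the frame border are kept — the arena wall
lies inside the frame. An optional 3×3 morphological opening (`cleanup`) is
off by default.

## Size calibration (RSS)

The number of pixels in one bee is estimated from the initial
`calibFrames = 500` frames (20 s at 25 fps; movies shorter than that are used
in full, with a warning). All region areas in the window are pooled, the
modal area *m* is found with a histogram (`binWidth = 4` px²; the modal value
is the median of the fullest bin, so it is insensitive to bin placement), and
areas inside the mode window `[0.5 m, 1.5 m]` count as single-bee samples.
The window rejects merged, roughly double-sized blobs — bees may already be
touching during calibration — and sub-bee specks. The RSS is the closed
interval `[min, max]` of the samples, and the body length is their mean major
axis. An optional relative margin (`rssMargin`, default 0) can widen the
interval to absorb pose-dependent area changes.

Two choices here were genuinely open:

* **Bounds from min/max rather than percentiles.** With the mode window
  already rejecting outliers, min/max keeps every legitimate pose; on clean
  footage the calibration then recovers the rendered body size essentially
  exactly (the tests require ±2 px² and ±0.5 px).
* **Closed interval.** A region whose area equals a bound "fits within" the
  range, so both ends are inclusive; the three size classes (`SBS` inside,
  `PBS` above, `NBS` below) partition all areas.

## Identification rules

The tracker's central restriction is that a bee cannot move farther than its
own body length between consecutive frames, so a bee's regions at *t−1* and
*t* must share pixels. Per frame, each region's size class is combined with
its overlap class against the previous frame's resolved per-identity masks
(`NBR`/`OBR`/`TBR` for zero/one/two-or-more overlapping identities):

* `SBS ∧ NBR` — a new bee; a fresh identity from an increasing counter
  (identities are never reused).
* `SBS ∧ OBR` — the common case; the identity is inherited.
* `SBS ∧ TBR` — two (or more) bees rendered as one single-bee-sized blob,
  i.e. truly stacked. Every identity is kept; its position is its linear
  prediction, constrained into the blob (projected to the nearest blob pixel
  when the prediction falls outside). The blob's *pixels* are partitioned
  among the identities (nearest predicted position; ties to the lowest
  identity) purely so that next-frame overlap tests stay well defined and
  per-identity masks stay disjoint — the blob is not claimed twice.
  When the predictions themselves (nearly) coincide — head-on pass-throughs —
  the partition falls back to nearest *previous mask*, which keeps the
  bookkeeping stable until the predictions separate again.
* `PBS ∧ TBR` — bees side by side as one plural-sized region; divided by
  **regional matching**: each parent identity's previous mask is rigidly
  translated, searching all integer offsets that keep its centroid within one
  body length (`searchRadiusFactor × bodyLength`) of its predicted position,
  to maximize overlap with the unclaimed part of the region. Parents are
  processed in decreasing order of best achievable score (ties to the lowest
  identity), contested pixels go to the earlier parent, leftover pixels
  attach to the nearest claimed mask, and a parent with zero achievable
  overlap is reported unmatched. Matching is translation-only: the underlying
  rigid-body assumption is that a bee does not change shape appreciably
  during a contact. The same greedy procedure generalizes to three or more
  claimants.
* Everything else (`NBS ∧ *`, `PBS ∧ NBR`, `PBS ∧ OBR`) — no processing. The
  region claims no identity; identities left without a region become
  **dormant** at their last position and take no further part in overlap
  tests, so a reappearing bee starts a fresh identity via `SBS ∧ NBR`.
  A post-hoc stitcher (`stitchTracks`; gap ≤ `maxGap` frames, distance ≤ one
  body length, bridged gaps linearly interpolated and flagged) is provided
  but off by default, because silent gap-bridging can manufacture identity
  where the evidence ended.

**Contention.** The rule list above leaves one situation undefined: a single
previous identity overlapping *several* current regions (a blob separating,
or a bee grazing two regions). Before the rules are applied, each such
identity is assigned to the one region whose centroid is nearest its
predicted position (ties to the lowest region label); the per-region overlap
classes are then computed from the assigned identities. In the uncontended
case this reduces exactly to the plain rules. All remaining ties anywhere in
the tracker resolve to the lowest identity, making the whole pipeline
deterministic.

## Trajectories and kinematics

Centers of mass of same-identity regions, connected in frame order, form the
trajectory. Speed is displacement × fps (px/s), acceleration the discrete
speed difference × fps, heading the displacement direction (radians, y
down). Values that need more history than exists are missing, not zero —
zeros would fake resting. Dormant frames are not emitted; positions are
unknown there. CSV export (`frame,id,x,y,area,speed,heading`, 6 decimals)
round-trips losslessly at that precision, and overlay PNGs draw each track's
polyline and identity on the source frames.

## Interaction events

An encounter is a maximal frame run with two centroids closer than
`contactDist` (default: the calibrated body length; 15 px matches the
reference footage). Pair episodes sharing a bee and overlapping in time merge
into multi-participant episodes; T1 is the first contact frame.

Classification parameters are not dictated by the tracking method and were
chosen to separate the category prototypes cleanly; all are exposed:

| parameter | meaning | default |
|---|---|---|
| `theta` | heading change that counts as "changed direction" | 45° |
| `phi` | incoming-heading cone for "same direction" | 90° |
| `vStop` | stop speed | 0.1 body lengths/s |
| `window` | frames before/after an episode for mean headings | 12 |

Precedence when rules co-fire: `multiple` (≥3 participants) > `waiting`
(exactly one participant stopped from T1 until separation) > `overlapping`
(the bodies merged into one single-bee-sized component — the tracker's
`merged` flag — with neither bee changing direction) > `touching`/`passing`
(direction changes; split by whether incoming headings differ by less than
`phi`) > `crossing` (no direction change, no merge). More specific evidence —
stopping, merging — wins over the default `crossing`. A bee that barely moved
in a heading window has no defined heading and counts as unchanged; if
exactly one bee changed direction, the touching/passing split still applies.
The encounter criterion is distance only; body orientation ("facing") is not
required, matching how encounter traces are normally read off distance
plots.

## The simulator: what it emulates, and what it does not

`simulateArena()` renders dark ellipses (hard fill, no antialiasing — so
segmentation ground truth is unambiguous; noise is added afterwards) on a
brighter frame, confined to a circular arena, and returns exact per-frame
positions, headings and behavioral states. Motion is a simplified
honeybee-inspired collision-and-wait rule: straight walking with Gaussian
heading noise, a sampled stop when within one body length of another agent
followed by a turn away (with hysteresis so pairs disengage), spontaneous
rests, and specular wall reflection with jitter, which produces
wall-following paths. Waits are drawn uniformly from configured bounds rather
than stimulus-dependent: the algorithm serves here as a plausible motion
generator, not as an aggregation model.

Defaults are the study conditions the package targets: 600 × 600 px frames,
25 fps, 1500 frames (one minute); 16 agents, matching the sixteen-bee arena
recordings the method is aimed at (the agent count for purely artificial
benchmark movies is a free parameter); 15 × 7 px bodies; speed 2.5 px/frame
(62.5 px/s, about 5 cm/s at the ~1 px/mm scale of such recordings — an
unhurried walking pace); bee/background gray levels 30/200; pixel noise
SD 2; rest probability 0.002/frame with 1–10 s rests; contact waits of
0.5–3 s.

**Scripted scenarios** (`scriptedScenario()`) realize each interaction
category exactly, with the episode boundaries recorded as ground truth. Every
scenario begins with a *lead-in*: each agent walks one full circle far from
the others, ending precisely at its scripted start pose. The circle serves
two purposes: all body orientations appear, so calibrating on the lead-in
(`trackConfig(calibFrames = sc$leadIn)`) sees the full single-bee area
range — mirroring the field practice of calibrating on initial, contact-free
footage — and the per-frame displacement never exceeds the configured speed,
honoring the tracker's motion restriction.

What the simulator does **not** emulate: body bending along the arena wall
(the known hard case for the linear-motion assumption), perspective and
lens distortion, lighting drift, shadows, antenna/leg articulation, and
photorealistic texture. Passing the synthetic suite therefore demonstrates
the correctness of the algorithmic pipeline — segmentation arithmetic,
calibration, the identity rules through merges and splits, metric
definitions — under the stated assumptions; it does not certify performance
on recordings whose physics violate them.

## Evaluation metrics

Association is per-frame greedy nearest-neighbour matching within radius
`r` (default one body length), one-to-one, ties to the lowest truth then
system identity; each system track is then assigned by majority vote to one
truth track, so a fragment counts toward exactly one trajectory. TFF of a
truth track is the number of system tracks assigned to it (≥1; undefined and
excluded, with a warning, if nothing covers it); TCF is the fraction of its
frames covered by its assigned tracks (0 when uncovered). Identity swaps are
counted as persistent (≥10 frame) changes of the matched truth identity
within one system track, so single-frame flickers during occlusions do not
count. An interaction event fails when some participant has no single system
track covering it from the contact frame through the episode end. Ratios are
reported at their conventional printed precision (2 decimals for TFF/TCF,
1 for percentages) — the association procedure itself admits variants in the
literature, so the rule used here is declared rather than inferred.

Self-comparison is the key sanity law: any trajectory set evaluated against
an identical copy must give TFF = 1, TCF = 1 and zero centroid error, which
the test suite asserts and `scripts/acceptance.R` recomputes.

## Numerical choices and degenerate inputs

* Comparisons: threshold test is `≥`; RSS interval closed at both ends.
* Negative background differences are clamped (dark-on-bright only), a
  deliberate dialect choice over absolute differences.
* All ties (overlap scores, distances, partition seeds) resolve to the lowest
  identity or label; the pipeline is fully deterministic, and simulation
  output is reproducible from the seed.
* Zero-agent movies track to an empty result rather than a calibration
  error; a movie with *some* foreground but an empty calibration window is a
  genuine error.
* An ellipse rendered partially outside the frame is clipped; a track with a
  single record predicts its own position (no velocity estimate).
* Translation search prefers, among equal-scoring offsets, the one nearest
  the prediction, keeping split masks stable frame to frame.

## Problem sizes used in the validation suite

The test suite runs entirely on generated data: oracle checks on masks up to
32 × 32; unit fixtures of 2–6 agents on 100–300 px arenas over tens to a few
hundred frames; the six scripted scenarios (181 frames, 260 × 260 px); and
one full-scale arena run at the default study conditions (16 agents,
600 × 600 px, 1500 frames), on which the tracker is required to reach mean
centroid error ≤ 1.2 px, zero identity swaps and TCF = 1 for every agent
wherever it is clear of the wall (more than two body lengths from it).
`scripts/acceptance.R` repeats the full-scale run from a caller-supplied
seed.

## Known limitations

* The linear-motion assumption degrades at the arena wall, where real bees
  bend and follow the curvature; wall-specific motion models are out of
  scope, and failures of this kind are expected to concentrate there.
* Regional matching is translation-only; a bee that rotates sharply *while*
  merged is matched by its untranslated shape.
* There is no appearance model: bees are interchangeable by design, so a
  truly ambiguous merge (symmetric, stationary, prediction-free) is resolved
  by deterministic tie-breaking, not evidence.
* A bee lost to dormancy returns as a new identity unless the off-by-default
  stitcher is enabled.
* Video files are not read directly; movies enter as numbered PNG/TIFF frame
  directories (or in-memory arrays), and overlays/frames are written as PNG
  directories.
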