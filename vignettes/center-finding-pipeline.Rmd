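---
title: "Analysing heated-arena center-finding trials with coolspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing heated-arena center-finding trials with coolspot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coolspot)
```

## The paradigm

In the center-finding variant of the "dry water maze", an insect is placed
on a floor heated to an aversive temperature inside an enclosure with no
visual cues; the only refuge is an inconspicuous cool spot (a 60 mm
diameter disc at 25 °C) at the geometric center of the enclosure. Over a
session of ten 5-minute trials the animal can learn to locate the spot
using the layout geometry alone. Four enclosure shapes of approximately
equal floor area (709 cm², within 3%) are used: a circle (⌀ 30 cm), a
square (edge 27 cm), an equilateral triangle (edge 40 cm) and an
asymmetric quadrilateral (edges 37, 24, 23, 26 cm; interior angles 67°,
80°, 100°, 113°).

`coolspot` implements the full analysis for this paradigm: arena geometry,
ingestion and calibration of video-tracker tables, per-trial behavioural
metrics, learning-slope estimation, isolation and featurization of
approach paths, and strategy clustering by dynamic time warping with
k-medoids. A synthetic trajectory generator with known strategy labels and
known learning dynamics makes every stage testable without recorded data.

## Arena geometry

Arenas live in a canonical frame: centimetres, x right, y up, cool spot at
the origin. Polygonal arenas are constructed by walking the printed edge
lengths under the printed interior angles. Because printed dimensions are
rounded to whole centimetres and degrees, the quadrilateral walk does not
close exactly; construction succeeds when the closure residual is below
1 cm (the realized residual is ≈ 0.4 cm) and the closing edge absorbs it.
The spot sits at the center of symmetry for the circle, square and
triangle and at the shoelace area centroid for the quadrilateral.
"Intersection of the medians" is ambiguous for quadrilaterals, so both the
area centroid (default) and the vertex average are computed; they differ
by a fraction of a centimetre for this shape.

Two geometric predicates matter downstream and are worth stating:

* **Containment is closed** — boundary points count as inside. The insects
  lean on the walls constantly; an open convention would misclassify
  genuine wall-following frames.
* **Perimeter distance is a magnitude** — `distance_to_perimeter()`
  returns the minimum Euclidean distance to the boundary curve for
  interior and exterior points alike, with no sign.

Camera calibration fits a least-squares similarity transform from the four
tracked landmark points (corners, or four perpendicular diameter ends for
the circle) to their canonical positions. Trackers report corners from an
arbitrary starting corner in either traversal direction, and image frames
are usually y-down, so the fit tries all four cyclic orders in both
directions with reflection allowed and keeps the minimum-RMS solution.

## Trial metrics

All durations are counted as frame counts times the *measured* median
frame interval — never the nominal frame rate — so files with slightly
irregular timestamps are handled correctly.

| parameter | default | rationale |
|---|---|---|
| stay threshold | 5 s | a successful stay is an on-spot bout of at least 5 s |
| stay gap bridging | 0.2 s | tracker jitter at the spot rim should not split a bout |
| approach window | 3 s | the path segment preceding a successful stay |
| on-spot exclusion | 95% | windows almost entirely on-spot are rim jitter, not approaches |
| rest speed | 0.5 cm/s | below this central-difference speed a frame counts as rest |
| wall band | 2 cm | roughly one body width; wall-following = frames within the band |
| interpolation gap | 0.5 s | longer tracking dropouts invalidate bout timing |

The stay threshold, window length and exclusion fraction are the
paradigm's stated rules; the rest-speed, wall-band and gap values are not
printed anywhere and are therefore configuration keys with the defaults
above. Latency is the time from trial start to the first on-spot frame;
if the spot is never reached the trial duration is recorded with a
censoring flag, and downstream slope estimation uses censored values at
the censoring value (a deliberate, simple convention — see limitations).
Occupancy maps pool frames over recordings of one shape into a 1-cm grid
of time proportions; cells outside the arena are masked, and occupied
cells always sum to one.

## Learning slopes

Time-on-spot proportions are square-root transformed and latencies are
log-transformed (`log(latency + 1)`; the offset is configurable) before
trend estimation, stabilizing their skewed distributions. The estimator is
deliberately a transparent two-stage procedure rather than a mixed model:

1. per animal, an ordinary least-squares line of the transformed response
   on trial number;
2. the arena-level slope is the mean of per-animal slopes, with
   `se = sd/√n` and a t-based 95% CI; a nonparametric bootstrap over
   animals (2000 resamples) provides an alternative interval.

This targets the same estimand as a random-intercept-and-slope mixed
model — the population mean per-trial change — while being fully
specifiable and testable by simulation. Numerical identity with mixed-model
coefficients is not claimed. Calibration is checked by simulation: over
100 metrics-level synthetic sessions (15 animals × 10 trials, residual sd
0.05 on the transformed scale) the t-CI covers the generating slope at
close to its nominal rate and the mean bias is far below half the mean
standard error.

Group comparisons use the two-sided Mann–Whitney U test (exact by
enumeration when `n1 + n2 ≤ 12` without ties, otherwise the normal
approximation with tie and continuity corrections) with Bonferroni
adjustment `min(1, m·p)`; the looming-response control is a 2×2 Pearson
chi-square in closed form.

## Approach paths and strategy clustering

For every successful stay, the 3 s of trajectory before its first on-spot
frame is isolated; windows truncated by the trial start are dropped (never
padded — padding would fabricate data that DTW then aligns), and windows
with more than 95% of frames already on-spot are excluded. Each window is
converted to its per-frame minimum distance to the arena perimeter and
min–max scaled to [0, 1] *per series*, so approaches from arenas of
different sizes and from different depths become comparable shapes. A
constant series scales to all zeros (pinned at its own minimum), avoiding
a division by zero.

DTW is computed by dynamic programming over monotone warping paths with
`|aᵢ − bⱼ|` local cost. Both common step patterns are available
(`symmetric1`; `symmetric2`, which double-weights diagonal steps including
the initial cell, the Sakoe–Chiba convention), along with an optional
Sakoe–Chiba band and path-length normalization. Series are compared at
native length; the kernel is verified against exhaustive warping-path
enumeration on short series.

**Choice of the band.** The operation-level default is unconstrained
warping, the common default of DTW packages. The *pipeline* default,
however, constrains warping to a 1-s band. The reason is structural:
unconstrained DTW is invariant to timing, and two of the paradigm's
strategies — wall-following-then-direct-approach and gradual/spiral
ingress — differ *only* in timing (both are monotone wall-to-center
rises). Without a band their DTW distance collapses to the noise level and
cluster-validity indices always favour merging them; with a 0.5–1.5 s band
the wall-dwell signal survives and the four strategies separate cleanly.
This mirrors how clustering settings are chosen in practice for this
paradigm: by optimizing clustering validity metrics.

Clustering is k-medoids (PAM: greedy BUILD, then best-improvement SWAP) on
the precomputed DTW matrix. DTW violates the triangle inequality and the
implementation nowhere assumes it. The procedure is deterministic: ties
break toward the lowest index, and the seed is recorded only for
provenance. Cluster numbering is canonicalized by descending size. The
distance-matrix silhouette (with the 0/0 → 0 convention and 0 for
singletons) is scanned over k = 2…8 to support the choice k = 4.

## The synthetic generator

The generator's role is to emulate the study conditions with known ground
truth: 15 animals per shape, 10 trials of 300 s at 30 fps, learning trends
on the transformed scales whose default magnitudes match the reported
circle-arena estimates (+0.026 per trial for √proportion, −0.185 per
trial for log-latency), and the four qualitative approach strategies.

Movement is generated as a guided random walk in *boundary-anchored*
coordinates: angular progress θ along the perimeter and an inwardness
coordinate u ∈ [0, 1] interpolating between the boundary point at θ and
the spot. Each archetype is a piecewise-linear target u-profile (wall
dwell then ramp; steady ramp; repeated ventures; out-and-return) plus
smoothed Gaussian noise on both coordinates. A free correlated random walk
cannot reproducibly realize these strategy shapes; the boundary-anchored
walk is the minimal construction that can, and it guarantees containment
in the convex arenas by construction (any stray point from added jitter is
reflected across the nearest boundary edge). Trials are assembled as
search (wall-band wander until the target latency), a labeled 3-s
approach, then stays on the spot alternating with center-out-return
excursions; unheated controls wander freely with no spot. Benchmark
"separation levels" set the within-archetype kinematic spread: `"high"`
uses tight noise around distinct templates (a positive control for the
clustering stage), `"zero"` collapses all archetypes onto one template (a
null in which recovered partitions must not correlate with labels).

What the generator does *not* emulate: biomechanics, thermal-gradient
taxis, tracker identity switches, or heterogeneous per-animal strategy
preferences. Passing the clustering benchmark therefore shows the DTW+PAM
machinery recovers planted structure of realistic shape and noise — not
that recorded cricket data contain exactly four strategies.

## Numerical choices and problem sizes

* Polygon closure tolerance 1 cm; arena areas validated against
  709 cm² ± 3%.
* Calibration fails above 1 cm RMS residual (configurable); collinear or
  duplicated landmarks are rejected as degenerate.
* PAM swaps require strict improvement (> 1e-12) so the swap loop
  terminates; costs are non-increasing by construction.
* Exactly-threshold stays count as successful (a 150-frame bout at 30 fps
  is 5.0 s).
* The test suite exercises trajectory sessions at reduced scale (3–4
  animals, 2–5 trials, 10–15 fps, 90–150 s trials) where only the
  mechanics are under test; estimator calibration runs at the full
  15 × 10 design over 100 metrics-level replicates, and the acceptance
  script additionally runs one full-scale trajectory session
  (15 × 10 × 300 s × 30 fps) end to end.

## Limitations

* Censored latencies enter the slope fit at the censoring value; with
  many censored trials the latency slope is attenuated toward zero.
* The two-stage slope estimator weights animals equally regardless of
  their number of usable trials.
* Exact reproduction of mixed-model coefficient tables, of printed
  cluster sizes, or of approach-path totals from the deposited recordings
  is out of scope: those depend on the original raw data and on
  clustering settings that are not printed.
* Approach windows shorter than 3 s are dropped, so very early arrivals
  contribute no path to the clustering stage.
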