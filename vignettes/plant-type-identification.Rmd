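---
title: "Identifying plant architecture from multi-view silhouette convex hulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying plant architecture from multi-view silhouette convex hulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planthull)
library(dplyr)
```

## The problem and the model

Cotton breeders distinguish two canopy architectures: the **cylinder type**,
whose upper and lower canopy have similar width, and the **tower type**, which
is wide at the bottom and tapers upward. The class matters for planting
density, photosynthetic efficiency and mechanized harvesting, but it is
usually scored by eye. `planthull` implements a quantitative pipeline that
reads a colored 3D point cloud of a single plant (as produced by SFM-MVS
photogrammetry), reduces it to rotational 2D silhouettes, summarizes each
silhouette by the corners of its convex hull, and classifies the plant from
the distribution of a discrete-curvature statistic over those corners.

The statistic is the **corner change rate**. For three consecutive hull
corners \((X_1,Y_1), (X_2,Y_2), (X_3,Y_3)\), with \(X\) the vertical (height)
coordinate and \(Y\) the lateral one,

\[
K' \;=\; \frac{\dfrac{Y_3-Y_2}{X_3-X_2} - \dfrac{Y_2-Y_1}{X_2-X_1}}{X_3-X_1},
\]

a second difference of the lateral-vs-vertical slope, i.e. a discrete
curvature with units 1/length. A near-cylindrical silhouette has almost
straight sides, so its corner change rates are small; a tower silhouette must
bend from a wide base to a narrow top, so at least one corner bends sharply.
The classification intervals are \(|K'| \in [0, 0.2]\) for cylinder and
\([0.4, 1.5]\) for tower, with a majority-count rule over all samples: a
plant is labeled cylinder exactly when strictly more of its samples fall in
the cylinder interval than in the tower interval (ties, including the
all-outside case, go to tower). Samples in neither interval count toward
neither class.

Three modeling choices deserve explanation:

* **Absolute value.** Along a convex chain the sign of \(K'\) is constant but
  opposite between the left and right chains (verified as a property test);
  the published ranges are nonnegative. We therefore pool \(|K'|\), which
  makes the two chains comparable.
* **Pooling.** All samples of all views and both chains are pooled per plant
  before counting. Whether per-view aggregation should precede pooling is not
  determined by the interval definition; pooling is the simplest rule
  consistent with the majority count.
* **Closed intervals.** Both intervals are closed; a rate of exactly 0.2
  counts as cylinder, exactly 0.4 as tower.

## The pipeline

`classify_plants()` runs, per plant:

1. **Read** (`read_point_cloud()`): ASCII PLY or XYZRGB text; colors are
   8-bit RGB.
2. **Orient** (`orient_plant()`): the reconstruction's frame is arbitrary, so
   the first principal component of the coordinates is rotated onto the +y
   (growth) axis. The eigenvector sign is fixed by putting the
   point-count-denser half above the centroid; note that the corner change
   rate is invariant under a vertical flip, so this sign never affects the
   label. A user-measured `rigid_transform()` can be supplied instead.
3. **Denoise**: `filter_statistical_outliers()` removes points whose mean
   distance to their `k = 30` nearest neighbors leaves the band
   \(\mu \pm 1\cdot\sigma\) (population moments over all points) —
   scattered reconstruction outliers; `filter_color()` keeps points with all
   RGB channels in \([41, 255]\), dropping the near-black noise that
   photogrammetry leaves along leaf and stem edges. Both defaults are
   configurable; the filters only ever delete points, never move them.
4. **Down-sample** (`downsample_voxel()`): voxel-grid centroids, default leaf
   2% of the bounding-box diagonal, to bound the cost of the multi-view
   stage. Retention is data dependent and reported, not enforced.
5. **Project** (`project_views()`): rotate about the vertical axis in 10°
   steps and record \((u, v) =\) (vertical, lateral) per view — 36 views.
   Coarser steps (e.g. 15°, 24 views) undersample the rate distribution;
   finer steps (5°, 72 views) add little information at double the cost,
   which is why 10° is the default.
6. **Normalize** (`normalize_view()`): uniformly rescale each view so its
   vertical extent is 5 model units. \(K'\) has units 1/length, so a fixed
   common scale is required for fixed numeric intervals to transfer between
   plants; 5 units matches the scale at which the intervals were derived.
7. **Hull and chains** (`quickhull()`, `split_chains()`,
   `simplify_chain()`): see below.
8. **Rates and label** (`chain_rates()`, `classify_plant()`).

## Convex hulls and silhouette chains

`quickhull()` is a from-scratch divide-and-conquer construction: the leftmost
and rightmost points seed a baseline, each recursion keeps the points
strictly outside the current edge and splits at the point farthest from it
(perpendicular distance), so no global angular sort is needed. Numerical
choices:

* *Strict-outside tolerance*: a point is outside an edge only if the signed
  area test exceeds `1e-12` scaled by the squared coordinate magnitude.
  Collinear boundary points are therefore **not** vertices — a
  piecewise-linear synthetic silhouette yields exactly its designed corners.
* *Tie-breaks*: "leftmost" is minimum lateral with ties broken by maximum
  vertical (rightmost symmetric, minimum vertical), which makes the seed
  vertices genuine corners when the extreme coordinate is shared by an edge.
* Output vertices are in counter-clockwise order and are always a subset of
  the input points.

`split_chains()` cuts the vertex cycle at the topmost and bottommost
vertices; the run down the low-lateral side is the left chain. Unique extreme
vertices belong to both chains. When several vertices tie for an extreme (a
flat cap, as at the top of a synthetic surface-of-revolution plant), the tied
vertices become chain terminals and the cap edge joins neither chain —
otherwise the near-horizontal cap would contribute an enormous spurious
curvature. Extreme ties are detected at `1e-9` of the vertical extent.

`simplify_chain()` is Douglas–Peucker with default tolerance 0.05 in
normalized units (1% of plant height). Dense reconstructed silhouettes carry
many sampling micro-corners whose triples produce meaningless rates;
published per-view hulls have on the order of six corners per chain, and a
1%-of-height tolerance reproduces that corner economy while keeping the
architectural corners. `tol = 0` is the exact identity.

Degenerate corner triples — two corners at (numerically) the same height,
which can survive at chain terminals after cap ties — are skipped rather
than made fatal: `corner_change_rate()` returns `NA` below a `1e-9` vertical
gap and `chain_rates()` drops those samples.

## The synthetic generator

`generate_plant_cloud()` builds a surface of revolution from a
piecewise-linear radius profile \((u_i, r_i)\), top to bottom. The two
presets encode the two architectures at the normalized working scale
(heights spanning 0.5–5.0 model units):

* cylinder: corners \((5.0, 0.72), (4.9, 0.78), (1.0, 0.80), (0.5, 0.72)\),
  chain \(|K'|\) ≈ 0.149 and 0.038 raw (0.134, 0.034 after normalization);
* tower: corners \((5.0, 0.02), (4.4, 1.30), (0.5, 1.42)\), chain \(|K'|\) ≈
  0.467 raw (0.421 normalized).

Both sets of rates sit strictly inside their respective intervals, so the
noise-free presets are label-recoverable by construction — that recovery is
what the end-to-end tests assert. Rings are sampled on an even height grid
with interior grid heights snapped onto profile corner heights, and azimuths
on an even grid starting at 0; with the default 360 azimuth steps every
10° view direction aligns with sampled azimuths, so the silhouette extremes
— and hence the hull corners and rates — are exact to floating point.

Emulated imperfections: *inward-only radial noise* (radius scaled by
\(1-|\varepsilon|\), \(\varepsilon \sim N(0,\sigma)\)), which preserves the
designed silhouette so hull-level ground truth survives; *black edge noise*
(points on the silhouette surface with all RGB channels ≤ 40, removed by the
default color filter); and *scattered outliers* (uniform in a 3×-inflated
bounding box, removed by the statistical filter). A symmetric-noise scan
would move the silhouette itself; that regime is intentionally excluded so
that the generator's truth labels remain exact.

`generate_dataset()` jitters each plant's corner half-widths by up to ±5%
and re-validates two things before accepting a jitter: the slope sequence
must stay monotone (convex silhouette), and every designed corner must
survive the default chain simplification after normalization. The second
rule exists because the cylinder preset's middle corners deviate from their
chord by only ≈ 0.065–0.089 normalized units — close enough to the 0.05
simplification tolerance that an adverse jitter could erase the architecture
the truth label describes. Ground-truth labels are derived from each
jittered profile's own normalized rates with the default intervals, so truth
and pipeline agree by construction even when a jitter pushes a rate into the
(0.2, 0.4) gap.

What the generator does **not** emulate: leaves, branches, occlusion,
non-convex silhouettes, anisotropic reconstruction noise, and realistic
point-density variation. Consequently, passing tests demonstrate the
correctness of the geometry and the statistic, not field performance on real
plants. One density artifact is worth knowing about: because every ring
carries the same number of points, narrow regions (e.g. the tower tip) are
much denser than wide ones, and the statistical filter — whose Gaussian band
is calibrated on the whole cloud — can trim such dense tips. The
classification majority rule absorbs this (spurious cap corners produce
rates far outside both intervals), but exact per-view sample counts are only
guaranteed on unfiltered clouds.

## Evaluation toolkit

`confusion_counts()`/`classification_metrics()` compute accuracy, precision
and recall with either class as positive; report output truncates to two
decimals (`format_metrics()`), because truncation is the convention the
reference tables follow for the cylinder row (raw values are always kept).
`fleiss_kappa()` (multi-rater) and `cohen_kappa()` (two raters) cover
inter-rater agreement on expert labels. `welch_t_test()` wraps
`stats::t.test()` for the two-class rate-difference test. `mean_ci95()` is
the Student-t interval used to summarize per-class rate distributions.
`kfold_cross_validate()` shuffles plants with a user seed, splits them into
contiguous near-equal folds, fits intervals (`fit_intervals()`, min–max or
central-95%) on the training folds and scores the held-out plants; it is
deterministic given the seed.

## Problem sizes and determinism

The test suite exercises the geometry oracles at deliberately modest sizes:
the quickhull brute-force cross-check runs 200 random instances of 10–60
points (the all-pairs half-plane oracle is cubic), filter oracles use
120–150-point clouds, and end-to-end recovery uses 20-plant datasets at
20 rings × 120 azimuth steps. Exactness tests (preset rates to 1e-6) use the
full 40 rings × 360 azimuth steps resolution. Every randomized test and the
generator itself are seeded; the classification path contains no unseeded
randomness.

## Known limitations

* The intervals were derived at a fixed normalized scale; skipping
  `normalize_view()` (supported via `normalize = FALSE`) makes the numeric
  intervals meaningless unless the input already has a comparable scale.
* The default voxel leaf (2% of the bounding-box diagonal) is close to the
  cylinder preset's corner-chord deviations; on low-feature silhouettes,
  voxelization plus simplification can remove every interior corner, leaving
  an empty rate profile (reported as a failed plant rather than silently
  labeled). For clean synthetic data, run with `denoise = FALSE` and
  `voxel_leaf = 0`.
* Non-convex canopy features are invisible to a convex hull by definition;
  the method reads only the outer silhouette envelope.
* The Fleiss/Cohen kappa functions assume complete rating tables (no missing
  cells).
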