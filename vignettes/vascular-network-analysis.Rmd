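---
title: "Quantifying cast vascular networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cast vascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vasctree turns a 3-D volume of a contrast-cast vascular network — as
produced by clinical CT, digital volume tomography, micro-CT or
synchrotron phase-contrast imaging of a radiopaque-cast organ — into
quantitative morphometry: a per-voxel vessel-diameter map, the volume
distribution by diameter, a reduced vessel-segment graph, the three classic
branching classifications, and a Gaussian-mixture clustering of segments
with cluster-validity diagnostics. This vignette explains the models the
package implements, the parameters that matter, and the choices made where
the methodology is genuinely open.

## The analysis chain

A run proceeds through five stages, each available as standalone functions
and orchestrated by `run_pipeline()`:

1. **Preprocessing.** A 3×3×3 median filter suppresses reconstruction
   noise; a 26-connected, density-windowed region grower segments the
   bright cast; `fill_holes()` repairs casting discontinuities (morphological
   closing with a ball of radius `max_gap/2`, plus filling of enclosed
   cavities, iterated to a fixed point so the result is idempotent).
2. **Local diameter.** `local_thickness()` assigns every vessel voxel the
   diameter of the largest sphere that contains it and fits inside the
   vessel (Hildebrand–Rüegsegger local thickness), computed as exact
   Euclidean distance transform → distance ridge → sphere painting, all in
   physical micrometres so anisotropic voxels are handled correctly.
   `diameter_histogram()` then accumulates physical voxel volume into
   half-open diameter bins; bin volumes sum *exactly* to the segmented
   vessel volume, which the tests assert as an invariant.
3. **Segment graph.** The mask is thinned to a topology-preserving curve
   skeleton (simple-point deletion with six directional subiterations), the
   skeleton is parsed into nodes (voxels with ≠ 2 skeleton neighbours;
   adjacent node voxels are merged into one junction) and polyline edges,
   short terminal spurs are pruned, and `reduce_to_segments()` emits one
   vessel segment per remaining edge: a piece of vessel between two
   bifurcations or between a bifurcation and a terminal end, with a unique,
   deterministic identifier.
4. **Branching classification.** After rooting the graph
   (`build_rooted_tree()`), `assign_generations()`,
   `assign_horsfield_orders()` and `assign_strahler()` label every segment:
   generations count junctions from the root (root = 1); Horsfield orders
   grow from the tips, incrementing at every junction; Strahler orders
   increment only when the maximal daughter order meets itself. On any tree
   Strahler ≤ Horsfield segmentwise and both are 1 exactly on terminal
   segments — properties the test suite checks against independent
   recursive oracles on randomized trees.
5. **Clustering.** Segments are clustered on (diameter, length) with
   Gaussian mixtures fitted by EM under six covariance parameterizations,
   the component count selected by BIC in the maximize convention
   `2·logL − p·ln n`, and the grouping compared with the order-based
   classifications through the Davies-Bouldin and Dunn indices. Labels map
   back onto the voxel grid through the same nearest-polyline partition
   used for segment volumes.

## Parameters, defaults, and why

| parameter | default | meaning |
|---|---|---|
| `min_component_voxels` | 8 | smallest 26-connected component (voxels) included in the thickness analysis; tiny specks are segmentation debris |
| `range_max` | 25 000 µm | upper cap on reported local diameters (25 mm spans organ-scale vessels) |
| `bin_width` | 2 × max voxel edge | one voxel of diameter resolution per histogram bin |
| `max_gap` | 3 voxels | widest casting discontinuity bridged by closing |
| `spur_voxels` | 5 | absolute terminal-spur pruning length |
| `adaptive_prune` | on | additionally prune terminal twigs shorter than the local vessel *radius* |
| `diameter_stat` | median | per-segment summary of sampled local thickness |
| `k_range` | 1–9 | candidate mixture sizes scored by BIC |
| `constellations` | EII … VVV | covariance families searched (see below) |
| EM `tol` | 1e-6 | relative log-likelihood convergence |
| EM `n_init` | 10 | k-means++-style restarts, best log-likelihood kept |

Three of these deserve justification.

**Adaptive spur pruning.** Thinning a thick tube produces short skeleton
twigs wherever the junction geometry is blunt. A fixed length cutoff cannot
separate them from genuine side branches across scales, but geometry can: a
terminal twig shorter than the *local vessel radius* at its attachment
never leaves the vessel body, whereas a real branch must. The pipeline
therefore prunes terminal edges shorter than `max(spur_voxels · voxel,
local radius)`. On phantoms this recovers the generated topology exactly.

**Median, not mean, segment diameter.** Near a junction the largest
inscribed sphere containing a daughter's polyline point still belongs to
the parent vessel, so thickness samples on the first stretch of a daughter
segment are inherited from the parent and biased high — on a strongly
tapering tree the polyline mean can overshoot the true daughter diameter by
some 15%. The junction-inflated stretch is always the shorter part of a
segment's polyline for tapering trees, so the median is immune to it; the
package defaults to the median and keeps the mean available via
`diameter_stat = "mean"`. The end-to-end phantom test holds the default
estimator to within 10% of ground truth (it lands near 2–3%).

**Six covariance constellations.** The EM implementation covers the six
canonical Gaussian-mixture covariance families — spherical, diagonal and
full, each shared or varying across components (EII, VII, EEI, VVI, EEE,
VVV in the volume/shape/orientation naming convention). The orientation-
constrained intermediates of the full 14-family taxonomy require a
constrained eigendecomposition M-step; six families already span the
complexity axis BIC needs, and the test suite cross-checks every family's
BIC against an independent mixture implementation. Restarts that collapse a
component onto fewer than d + 1 points are rejected as likelihood spikes
(the classic EM singularity) rather than reported as fits; genuinely
degenerate but meaningful inputs (point masses) survive through a ridge of
1e-6 × the data variance, with a warning.

Feature columns are log10-transformed and standardized by default:
diameters and lengths are positive and span orders of magnitude in a
vascular tree, and unstandardized Euclidean validity indices would be
dominated by whichever column has the larger numeric range. Raw features
remain available (`log_transform = FALSE`, `standardize = FALSE`).

## Conventions and numerical choices

* Grids are stored as native R arrays indexed `[x, y, z]` with voxel-center
  physical coordinates `origin + (index − 1) · spacing`, all lengths in µm.
* Vessel uses 26-connectivity, background 6-connectivity (the standard
  digital-topology pairing); the region outside the grid counts as
  background for distance transforms and thinning.
* The median filter reflects at borders, avoiding edge darkening.
* The inscribed-sphere radius at a voxel is its distance to the nearest
  background voxel center; painted spheres use strict inclusion. The
  brute-force validation oracle implements the same definition by direct
  enumeration, and agreement is required within half a voxel diagonal.
* Segment identifiers are assigned in a deterministic traversal order
  (sorted by endpoint anchor voxels, then polyline), so identical inputs
  give bit-identical tables; the pipeline asserts this by re-running.
* Root selection: the terminal node incident to the largest-diameter
  segment; ties break toward the smaller node id. Cycle-closing segments
  (anastomoses, casting artifacts) are excluded from ordering and reported,
  never silently dropped.
* Junctions with three or more daughters are one junction: Horsfield
  increments there regardless, Strahler only when the maximal daughter
  order appears at least twice; single-daughter pass-throughs (possible
  after cycle removal) propagate labels unchanged.
* Davies-Bouldin uses mean distance-to-centroid scatter; Dunn uses
  single-linkage separation over complete-linkage diameter. Both are
  Euclidean, invariant under rigid motion and isotropic scaling, and agree
  with a 4-point hand computation to 1e-9 in the tests. Coincident
  centroids (DB) and all-singleton groups (Dunn) report `Inf`;
  single-group labelings are reported as undefined rather than an error.

## The synthetic phantom: what it emulates, and what it does not

`phantom_spec()` + `generate_tree()` + `rasterize_tree()` produce a
branching tubular network with complete ground truth: per-segment
endpoints, radii, lengths, parentage and true generation/Horsfield/Strahler
labels. Daughter radii taper by `radius_ratio` (default Murray's law,
2^(−1/3), so daughter radii cubed sum to the parent's cube), lengths by
`length_ratio` (default 0.8); the root length defaults to 3 × the root
radius, a typical proximal length-to-radius ratio. Daughters sit on a cone
(default half-angle 37°) with azimuths spread evenly and rotated per level;
self-intersecting placements are rejected and resampled deterministically
under the spec's seed. Segments rasterize as capsules — cylinders with
hemispherical caps — so junctions have no notches; casting gaps carve
spheres of 1.5 × the local radius at random positions of flagged segments,
emulating cast discontinuities, and `degrade_volume()` (Gaussian blur in
physical units, seeded noise, resampling) emulates viewing the same cast at
the coarser voxel scales of the lower-resolution modalities.

What passing phantom tests does **not** show: real casts have elliptical
and tapering lumina within a segment, wall irregularities, touching
parallel vessels, imaging artifacts (beam hardening, phase fringes) and
anastomotic loops as the rule rather than the exception. The phantom family
contains loops only as optional extras, and segmentation thresholds on real
greyscale data remain the user's scientific responsibility. Phantom results
validate the *computational chain*, not any particular biological claim.

## Validation problem sizes

The shipped tests validate on sizes chosen to exercise every code path
while staying comfortable on a laptop: oracle comparisons on ≤ 16³ random
masks; branching-label oracles on 100 random trees of up to 200 segments;
end-to-end recovery on a depth-6 symmetric binary phantom with a 40-voxel
root radius (~2.2 million vessel voxels in a ~500³ grid), which must come
back with exactly 63 segments, 6 Strahler orders, and segment diameters
within 10% of truth; and BIC recovery on 2-D mixtures with 5σ separation at
600 points each. `scripts/acceptance.R` re-runs the same computations from
scratch and writes the resulting numbers as JSON.

## Known limitations

* The thinning-based skeleton can wander by a voxel inside near-isotropic
  blobs; segment lengths very close to junctions are correspondingly less
  reliable than diameters.
* Segment *lengths* shorten where daughter tubes overlap near a junction
  (the skeleton bifurcates only where the tubes separate); diameters are
  robust to this, lengths are not corrected for it.
* `fill_holes()` with a large `max_gap` will happily bridge vessels that
  merely pass close by; choose it at the scale of genuine cast gaps.
* GMM clustering on (diameter, length) of a *perfectly* self-similar
  phantom sees as many point-clusters as there are levels — on real,
  noisy morphometry the BIC-selected k is typically much smaller than the
  number of branching levels.
* Wall thickness of hollow structures (true wall metrology) and
  artery/vein classification are out of scope.
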