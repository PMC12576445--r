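---
title: "Methods behind canopy3d: from orchard point clouds to tree-level traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind canopy3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`canopy3d` turns multi-source orchard point clouds into per-tree canopy and
floral traits. Two mapping sources are assumed: a LiDAR-like survey at bud
burst, dense, geo-referenced and carrying per-point return intensity, and a
photogrammetric drone survey at bloom, sparser and carrying RGB colour. The
pipeline has seven stages: pre-processing (outlier removal, ground
filtering, canopy height model), tree segmentation, grid positioning,
skeleton-based cross-source registration, skeleton refinement (support
removal, gap filling, branch counting), convex-hull crown morphometrics and
blossom-cluster analysis. A synthetic-orchard generator provides
ground-truthed inputs for every stage, and everything the test suite and
the acceptance script assert is computed on that generator's output.

This vignette records the models and procedures each stage implements, the
parameters that matter, the numerical choices that were genuinely open, and
what the synthetic evidence does and does not establish about real data.

# Pre-processing

**Statistical outlier removal.** A point survives if its mean distance to
its `k` nearest neighbours (default `k = 16`) is at most the global mean of
that statistic plus `std_ratio` standard deviations. On a single tree with
one point density, `std_ratio = 1` behaves as commonly tuned. On a whole
orchard scene the statistic is bimodal — terrain returns are sparser than
canopy surfaces — and a one-standard-deviation fence removes the sparser
class nearly wholesale (it also trims the top ~16% of a perfectly
homogeneous cloud). The pipeline configuration therefore defaults to
`std_ratio = 2.5` for scene-level denoising while the function default
remains 1.0 for per-tree use.

**Ground filtering.** The ground/above-ground split follows the
cloth-simulation idea: a grid of cloth particles (spacing
`cloth_resolution`, default 0.5 m) settles onto the terrain from below.
Each relaxation sweep averages the four neighbours (tension), adds a small
upward restoring step (2 cm, the gravity analogue in the settled state) and
clamps the cloth from above by the lowest point in each cell. Borders are
extrapolated linearly — replicated borders would flatten sloped terrain and
drag the cloth downhill, which costs several percent of ground recall on a
5 degree slope. Cells outside the data footprint inherit the nearest
constrained cell before relaxing, otherwise bilinear interpolation at the
scene edge mixes in unsettled cloth. Points within `class_threshold`
(default 0.05 m) of the cloth are ground.

**Canopy height model.** Per cell (default 0.05 m), CHM = max above-ground
z minus terrain interpolated at the cell centre, clamped at zero, reported
in centimetres; empty cells are no-data. Terrain interpolation is linear
barycentric over the Delaunay triangulation of the ground points with a
nearest-neighbour fallback outside the hull. Adding the same planar ramp
to ground and canopy leaves the CHM unchanged within interpolation error
(a property the tests assert).

# Tree segmentation and positioning

The CHM is mapped to an 8-bit image (0 = ground or no-data, 255 = tallest
cell, rounding half-down), binarised by a tiled local Otsu threshold
(window 65 px, global fallback for small rasters and low-contrast tiles),
consolidated by a morphological closing (disc radius 5 px) and cleaned by
an opening (disc radius 2 px). The closing is needed for leaf-off trees:
a bud-burst canopy projects as thin scattered branch returns, not a filled
disc, and without closing each crown fragments into several components.
Closing at 5 px (0.25 m) cannot bridge planting distances of 1 m or more.
Connected components below `min_area_px` (default 25) are dropped; the
rest become tree masks. Points are assigned to the single mask that
contains them; where masks overlap, the nearer mask centroid wins and
exact ties go to the lower tree id.

Slot bookkeeping follows planted rows: expected positions are linear
interpolations between row end trees; a slot with no detection within half
a planting distance is a gap; a matched instance with fewer than
`min_points` (default 200) points is dead.

The tree centroid is the arithmetic mean of the overhead projection of the
lowest 10% of points by height — trunk returns dominate that slice, so the
estimate tracks the stem rather than the crown. Selection is tie-inclusive
at the cutoff height so flat layers are used symmetrically; a hook for
density weighting exists but equal weights are the default. Precise
surveyed coordinates attach to grid cells verbatim where available;
remaining cells are mapped through a least-squares 2D similarity transform
fitted from local centroids to the reference frame (at least two
referenced cells required).

# Skeleton extraction and registration

**Contraction.** The cloud is voxel-thinned (0.02 m), then contracted for
`contraction_iters` (20) sweeps: each point moves toward the centroid of
its neighbourhood ball (`contract_radius`, default 0.06 m — of the order
of the thickest tube diameter so the whole cross-section contributes),
with the displacement projected orthogonally to the local principal
direction. The projection is what makes the procedure usable: without it,
points slide along branches and clump into beads separated by more than
the graph-building radius, which breaks connectivity downstream. A small
attraction term (default 0.05) to the original positions bounds the
residual radial offset at roughly `attraction x tube radius`. Contracted
points are pooled into skeleton nodes on a 0.03 m voxel grid and joined by
a Euclidean minimum spanning tree restricted to short edges. On synthetic
cylinders of 5 cm radius the node set lies within a few millimetres of the
true axis.

**Coarse registration.** Fast-global-registration style: 33-bin FPFH
descriptors on both node sets, mutual nearest-neighbour feature matches,
then up to `max_iters` (50) random-sample consensus restarts, keeping the
transform with the smallest inlier RMSE. One deliberate departure from the
surface-cloud recipe: the Darboux frames are built on the local *tangent*
direction (principal eigenvector, sign toward +z) rather than on surface
normals. Skeletons are curves; surface normals are undefined on them, and
with PCA "normals" the correspondences were essentially random, while with
tangents about three quarters of mutual matches are geometrically correct
— enough for four-point RANSAC to succeed almost surely within the restart
budget. The feature radius defaults to 20x the mean node spacing, i.e. of
the order of a branch length, so histograms see real structure.

**Fine registration.** Point-to-point ICP from the coarse initialisation:
alternate capped nearest-neighbour correspondences (`max_corr_dist`,
default 0.2 m) and closed-form rigid fits, with a monotone non-increasing
objective and a relative tolerance of 1e-6 (cap 100 iterations). On the
synthetic suite (rotations to 30 degrees, translations to 1 m, 1 cm node
jitter) the recovered motion is within 2 degrees and 2 cm of truth and
fine strictly improves coarse in every trial.

Registration direction is drone onto lidar: the lidar frame carries the
precise geo-coordinates. Blossom-coloured points are masked out before
skeletonizing the drone cloud, since flower blobs contract into spurious
nodes that carry no structural information.

# Skeleton refinement

The trunk radius is estimated as the median horizontal distance of slab
points (0.2-0.4 m above the base) from the slab centre; the centre is
seeded with the component-wise median and refined by trimming at twice the
median distance, which keeps a support post occupying a third of the slab
from inflating the estimate several-fold. Distance parameters derive from
this radius: R-NN graph radius `2 r_trunk`, intensity-transfer and
blossom radii `r_trunk`.

The tree graph connects nodes within the R-NN radius with squared
Euclidean edge weights (short hops are preferred over long skips); the
base is the lowest node; tips are degree-one vertices plus local maxima of
shortest-path distance from the base, computed per connected component so
that occlusion-broken fragments still receive tips.

Support removal is two-pass. Graph pruning keeps exactly the union of
Dijkstra shortest paths from each component's lowest vertex to its tips —
skeleton material that no base-to-tip route traverses (wires crossing the
crown, off-path strands) disappears. Intensity pruning transfers mean
cloud intensity onto each node through an R-NN ball of radius `r_trunk`
and removes crown nodes brighter than the tree mean by `alpha` (default 1)
standard deviations *and* by an absolute margin of 0.1; the margin keeps
near-uniform reflectivity untouched, since a pure z-score fence always
clips the upper tail. Support material (metal, treated wood) reflects
around 0.9 on the normalised scale against roughly 0.3 for bark, so both
posts and wires clear the fence. The portion of a post below the crown
survives both passes but is disconnected once the wire is gone; gap
filling then drops it, because reconnecting it to the trunk would require
voxels flagged by the removed-support screen.

Gap filling voxel-downsamples the original cloud (0.02 m), discards voxels
within `r_trunk` of any removed node (the screen is absolute — the tests
assert zero reintroductions), clusters the pruned skeleton into Euclidean
components, and reconnects every broken component to the largest component
along Dijkstra shortest paths whose intermediate vertices are admissible
voxel centroids. Anchoring on the largest component matters: after support
removal the globally lowest node may sit on a pruned post stub. A final
path-union pass on the reconnected skeleton clears fragments the bridging
step attached off the main paths.

Smoothing decomposes the skeleton into maximal paths between junctions,
applies a moving average (window 5 nodes, junctions held fixed) and
resamples each path to uniform spacing; junction count is preserved.

Branch counting takes the trunk as the shortest path from base to the
highest tip; every other tip contributes the off-trunk portion of its
shortest path to the base, anchored at the trunk vertex where it joins.
Branches shorter than `min_len` (0.1 m) are discarded; branches whose
off-trunk vertices are contained in a longer branch, or that run within
the graph radius of one for most of their length, are treated as
duplicates (several tips can sit on one branch, and contraction can leave
a short parallel strand). This is a first-order branch count by
construction: a forked branch contributes one path per tip. On the
20-tree synthetic suite the count is exact without noise and within one
branch under 1% outlier contamination.

# Canopy and floral traits

Maximum height is the z-range in centimetres. The crown region starts
where material first appears outside the trunk cylinder (radius
`2 r_trunk`): the trunk cluster is grown by density clustering within the
cylinder from the lowest point, and its top is capped at that
branch-emergence height — without the cap a central leader extends the
trunk cluster to the apex and the crown collapses to the top tuft. Crown
volume and surface come from the 3D convex hull (an incremental
quickhull-style construction with facet-integration volume, implemented in
C++ and checked in the tests against an independent brute-force facet
oracle to 1e-9 relative); projection area from the 2D hull of the x-y
projection (shoelace formula); crown diameter is the larger of the
east-west and north-south extents, with east-west taken as the x axis of
the projected frame. Traits are computed on the support-pruned cloud by
default; supports can only add height and hull volume, and the tests
assert height never increases after pruning.

Blossom extraction converts RGB to luma greyscale and keeps points at or
above a per-tree global Otsu threshold (an excess-colour index could be
substituted; on the generator's colour model, near-white blossom against
green and brown wood, greyscale Otsu separates at recall and precision
above 0.95). Surviving bright points within `r_trunk` of a skeleton node
are removed as sun-lit bark. Clusters form by DBSCAN with radius
`r_trunk` and a specialist floor of 20 points; a hard rule sends clusters
under 50 points to noise; K-means (k = 2, 10 restarts, fixed seed) over
z-scored size features — point count, hull volume, maximum PCA extent —
separates single from multiple flowers, with the smaller-feature group
labelled single. When the two candidate groups differ by less than 1.5x
in mean size the population is treated as homogeneous singles: K-means
always returns two groups, and without this guard a pure-single tree
would send half its flowers through the split path. Multi-flower clusters
are split recursively, halving the DBSCAN radius per level and
re-classifying the pieces against the fitted K-means model, to depth 4;
exhausted leaves are forced single and flagged. Strata are equal thirds
of the crown z-span with bands closed above (a boundary point belongs to
the band below it, so the crown base itself is in the lower band).
Cluster volumetrics mirror the crown metrics, plus a voxel-occupancy
volume as an auxiliary. Each cluster attaches to the branch whose
polyline is nearest to its centroid (ties to the lower branch index;
centroids beyond 0.5 m stay tree-level only).

# The synthetic orchard

The generator is the package's evidence base, so its defaults are the
study conditions. A tree is a vertical trunk continuing into a central
leader (height 2.5 m, trunk radius 4 cm, clean trunk to 0.8 m), with 5-10
lateral branch tubes at golden-angle azimuths and 35 degree elevation,
junctions spaced along the lower leader so the leader remains the apex.
Surface sampling noise is 5 mm. The trunk is sampled from 2 cm above
grade — ground vegetation occludes the collar in real scans, and the
lowest centimetres are genuinely ambiguous between terrain and stem for
any distance-based ground filter. Supports are a vertical post 0.45 m
from the stem plus a horizontal wire through the crown; support intensity
is N(0.9, 0.05) against N(0.3, 0.05) for wood, per-cloud min-max
normalised. The lidar view carries intensity at bud burst (no blossom);
the drone view is a 40% density resample with 4 mm extra noise, coloured
(wood brown, branches foliage-green, blossom near-white, sigma 10 per
channel), displaced by a random rigid motion (rotation to 25 degrees
about z plus small tilt, translation to 0.5 m) recorded in the truth.
Blossom blobs (sigma 1 cm, 80-120 points) hang 5 cm off the branch axis
on pedicels; touching pairs are planted 5 cm apart around shared anchors
with at least 0.2 m between anchors. Orchard scenes place trees on the
planting grid (default 4.0 x 3.5 m) with 10 cm planting jitter over a
sloped plane sampled at 150 points per square metre with 5 mm noise —
comparable to the canopy surface density, which is what makes scene-level
outlier removal meaningful.

What the generator does *not* emulate: leaves and seasonal foliage,
occlusion shadows from a fixed scan trajectory, registration drift inside
a single survey, intensity variation with incidence angle and range,
mixed-species rows, wind-blown double surfaces. Passing the suite
therefore shows the algorithms are correct on clean tubular geometry at
realistic densities; it does not certify performance on heavily occluded
or leaf-on field scans.

# Problem sizes and determinism

The shipped tests and the acceptance script use a 4 x 5 orchard (19 trees,
one gap, about 160k points), 20-tree branch suites, 20 random
registration trials and two blossom trees — sizes chosen so the whole
evidence base recomputes in a few minutes on one core. All stochastic
steps (generator, RANSAC restarts, K-means) take explicit seeds and
save/restore the caller's RNG state; a repeated pipeline run with the same
seed writes byte-identical trait tables, which the suite asserts.

The pipeline configuration is a single YAML document validated against the
package defaults; unknown keys are rejected outright, and every run writes
its resolved configuration next to the outputs.

# Known limitations

Branch counting is first-order only (no second-order hierarchy, no
cylinder fitting or diameter estimation). Intensity pruning needs a
genuine reflectivity contrast between supports and wood; on sensors where
that contrast vanishes, the graph pass and the admissibility screen still
remove wires and isolated stubs but a post fused to the trunk would
survive. The cloth filter assumes terrain visible at the grid scale —
dense continuous ground cover would bias the cloth upward. The hull-based
crown volume is convex by construction and overestimates concave crowns;
that bias is shared with the convex-hull definition of the trait itself.
Registration assumes the two views differ by a rigid motion; growth
between survey dates that deforms the tree is outside the model.
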