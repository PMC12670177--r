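---
title: "Canopy effective volume from LiDAR point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy effective volume from LiDAR point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyEV)
```

## The problem and the model

LiDAR clouds of fruit-tree canopies sample the *surfaces* the laser hits:
outer foliage, branches, some interior structure. Any estimator that wraps a
surface around these points — a convex hull, an alpha-shape, their sliced
variants, or an occupancy-voxel count — measures the spatial envelope of the
point distribution. Canopies of orchard trees are highly porous, so the
envelope can exceed the amount of actual canopy material severalfold, which
matters when the volume drives spray dosing.

`canopyEV` separates the two quantities explicitly:

$$V_e = V_m \cdot EVC, \qquad EVC = EC_{xoy} \cdot EC_{xoz} \cdot EC_{yoz}.$$

$V_m$ is an envelope volume, computed from a closed alpha-shape mesh.
$EVC \in (0, 1]$ is an *effective volume coefficient* that estimates the
solid fraction of that envelope from the cloud's three orthogonal
projections. The construction mirrors a physical laboratory procedure in
which a canopy is back-lit from three orthogonal directions and the shaded
fraction of each silhouette is multiplied together: porosity visible in any
single direction reduces the coefficient, and a region only counts as solid
if every direction sees material there. The multiplication of exactly three
plane coefficients, without re-normalization, is deliberate: it is the
instrument being emulated.

### Envelope reconstruction

The alpha-shape at radius $\alpha$ keeps every tetrahedron of the 3D
Delaunay tetrahedralization whose circumradius is at most $\alpha$; the
surface is the set of faces incident to exactly one kept tetrahedron.
$\alpha$ is a length in meters throughout (a circumradius bound). Two rules
make the parameter density-aware:

* baseline $\alpha_{base} = k \cdot d_{avg}$ with $k = 5$, where $d_{avg}$
  is the exact mean nearest-neighbour distance of the cloud (no sampling;
  duplicate points contribute zero and are kept, because they carry real
  density signal);
* if the boundary at the current $\alpha$ is not closed, $\alpha$ grows by
  $0.5 \cdot d_{avg}$ per iteration until it is.

"Closed" means: zero boundary-edge defects (every edge on exactly two
surface triangles) and a single connected surface component enclosing
positive volume. Disconnected surface islands below 1 % of total surface
area are discarded before the test — without this rule a single stray point
cluster would block closure at every $\alpha$. After 50 iterations the
convex hull (the $\alpha \to \infty$ limit) is returned with a warning; it
is guaranteed closed and upper-bounds the volume.

The mesh volume is the divergence-theorem sum
$\left|\sum_t \vec V_0 \cdot (\vec V_1 \times \vec V_2)\right| / 6$ over
consistently outward-oriented triangles. The absolute value sits outside
the sum, not inside: per-triangle absolute values would make the result
depend on the coordinate origin and inflate non-convex meshes. For meshes
that are star-shaped about the origin the two readings agree term by term,
which is why the distinction is easy to miss; the origin-translation
invariance of the signed sum is asserted in the test suite.

The Delaunay engine (2D and 3D incremental Bowyer–Watson with cavity
validity checks and deterministic symbolic perturbation for degenerate
inputs) is implemented in C++ in this package, and is validated in the
tests against `deldir` in 2D and against a brute-force empty-circumsphere
audit in 3D.

### The effective volume coefficient

Per projection plane (`xoy`, `xoz`, `yoz`):

1. **Projection** drops one coordinate and keeps it per point (it becomes
   the thickness signal below).
2. **Voxelization** bins the 2D points into square voxels of side
   $VS = d_{avg}$ (half-open bins anchored at the 2D minimum corner);
   a voxel is *effective* if it contains at least one point.
3. **Contour**: a 2D alpha-shape of the projected points, grown with the
   same dynamic scheme ($5 \cdot d_{avg}^{2D}$ baseline, $0.5 \cdot
   d_{avg}^{2D}$ steps) until every point is covered. A voxel is
   *in-contour* if its center is covered by the complex **or enclosed by
   its outer boundary**: interior windows of the complex — through-gaps in
   the canopy — count as in-contour (resolved by a flood fill from the
   raster border), because they are exactly the porosity the silhouette
   instrument sees. Gaps that reach the outline (notches) stay outside,
   as they would in a shadow image.
4. **Partitions**: aligned $5 \times 5$-voxel blocks (integer division of
   voxel indices, so each voxel belongs to exactly one block). Each block
   with points gets weight $W = \max - \min$ of its points'
   dropped-coordinate values — the local canopy thickness along the view
   direction. Blocks inside the contour with $W = 0$ (no points, or
   coincident dropped values) receive the arithmetic mean of their
   non-zero eight-neighbours, all blocks simultaneously per round
   (Jacobi-style, so the result cannot depend on block iteration order),
   repeated until no zero remains; unreachable zeros raise an error.
5. **Coefficient**: $EC = \sum_i W_i\, n^{ev}_i / \sum_i W_i\, n^{av}_i$
   over blocks with in-contour voxels, where $n^{av}$ counts in-contour
   voxels and $n^{ev}$ occupied in-contour voxels.

The thickness weighting is what keeps thin silhouette edges (where voxels
are legitimately half-empty) from dominating the coefficient, and
conversely makes emptiness in *thick* parts of the canopy — real interior
porosity — expensive.

### Why VS comes from the 3D cloud

The voxel size is $vs\_multiplier \times d_{avg}$ with the default
multiplier 1 and $d_{avg}$ computed on the **3D** cloud. An alternative is
each plane's own projected 2D mean nearest-neighbour distance
(`vsSource = "projected2d"`, provided). The 3D default is a deliberate
design decision, for a quantitative reason: for any approximately
homogeneous point process the 2D mean nearest-neighbour distance is
$\approx 1/(2\sqrt{\lambda_2})$, so voxels of that size contain on average
$0.25$ points *independent of density* — in-contour occupancy then
saturates near $1 - e^{-0.25} \approx 0.22$ no matter how dense the scan,
and the coefficient stops measuring porosity and starts measuring a
constant of the Poisson process. With the 3D $d_{avg}$, expected 2D points
per voxel scale like $0.3\,\lambda^{1/3} t$ with local canopy thickness
$t$: dense solid material saturates toward occupancy 1 and porous or thin
regions fall away from it, which is the behaviour the shadow-instrument
analogy requires. On real scans with strongly anisotropic scan-line
structure the projected-2D variant may be preferable; it is a switch, not
a code change.

## Preprocessing and segmentation

* **Radius outlier removal** (radius 0.2 m, ≥ 20 neighbours): a point is
  kept iff at least 20 *other* points lie within 0.2 m, every decision made
  against the original cloud (single pass — deterministic and
  order-independent; the alternative cascading reading is a different
  operation). The query point is not counted: the two readings of
  "neighbourhood size" differ by one and this one is documented.
* **Leveling**: RANSAC plane fit (inlier distance 0.05 m, 1000 hypotheses,
  seed 42 by default so the stage is reproducible; the global RNG state is
  restored), normal oriented to positive Z, least-squares refinement on the
  inliers, minimal rotation to vertical, fitted plane shifted to $z = 0$.
* **Ground filtering**: the package ships a grid filter — per-cell low
  z-quantile floor estimate (0.5 m cells, empty cells filled from
  neighbours), points within `class_threshold` (0.3 m) of the floor are
  ground. The cloth-simulation parameter set (`csfParams`, defaults FALSE,
  0.3, 0.1, 500, 3, 0.65) is accepted in full so configurations are
  portable; `method = "csf"` requires an external cloth-simulation backend
  and raises a pointed error when none is present. A filter that estimates
  the floor from the cloud itself cannot return a cloud untouched when
  there is no ground in it; scenes without ground should skip the stage.
* **Rows**: Gaussian KDE of Y (bandwidth: Scott's rule, or fixed), grid
  step bandwidth/4; KDE minima with prominence ≥ 10 % of the density
  maximum become cuts; half-open intervals assign every point to exactly
  one row.
* **Columns**: per-bin maximum height along X (bins 0.05 m — resolving
  1 m plant spacing with ~20 bins per tree), then three screening stages
  on the profile's local minima: drop troughs shallower than `min_depth`
  against either adjacent peak (default 0.15 × row height range); among
  troughs closer than `min_spacing` (0.5 m) keep the lower, ties to the
  left; reinstate spacing-removed troughs deeper than `sig_depth` (default
  0.30 × range) against both peaks — reinstated troughs are never removed
  again. Adjacent peaks use the prominence convention (walk outward until
  the profile drops below the trough): without it, noisy staircase
  descents hide deep junction troughs behind shallow intermediate minima.
  Only reinstatement of detected minima is implemented; the screening
  stages never invent troughs.

## Reference estimators

ASBS and CHBS split the Z extent into 10 equal layers (a point exactly at
the top belongs to the top slice) and sum per-layer 2D area × thickness;
ASBS uses the same dynamic 2D alpha-shape as the contour step (per-layer
$d_{avg}$), CHBS the 2D convex hull, so CHBS ≥ ASBS always. The voxel
estimator VB counts occupied 3D voxels at voxel size = canopy diameter / 15,
diameter read as the larger of the x and y bounding-box extents (the
conservative reading). The volume reduction rate of the effective volume
against a comparison method is $(V_{cm} - V_{EV}) / V_{cm}$.

## What the synthetic generator emulates — and what it does not

The generator is the package's study instrument, so its defaults are fixed
once, from the geometry of a standardized tall-spindle orchard and the
scanner's error budget, and are not tuning knobs:

* **Envelope**: two stacked frusta plus a cone of equal heights (the same
  three-section model used for manual canopy measurement), base radius
  0.6 m, height 3.5 m; radius profile 1 / 0.8 / 0.55 / 0 of the base.
* **Cross-section**: two cosine harmonics on the radius —
  5 broad lobes of amplitude 0.15 (scaffold branches) and 14 narrow
  corrugations of amplitude 0.28 (gaps between individual branches). Both
  keep the envelope volume closed-form
  ($\times (1 + a^2/2 + b^2/2)$), and their phases are fixed at zero so
  that half-space sector volumes are exactly half the band volume. The
  corrugation is load-bearing for realism: it gives the surface the deep,
  narrow concavity that separates voxel counting (which pads rough
  surfaces with shell voxels) from sliced alpha-shapes (which shrink-wrap
  them), reproducing the canonical envelope-estimator ordering.
* **Porosity**: spherical interior voids (validated non-overlapping,
  strictly interior — overlap is an error, keeping the truth analytic),
  full horizontal slabs, and *sector voids* (a horizontal band emptied on
  one y half-space). The porosity preset `spindlePorosity(f)` uses two
  nested sector gaps on alternating sides with widths solved from the
  closed-form band volume: sector gaps keep the canopy connected, carve
  the reconstruction the way real crown gaps do, and are visible to the
  projections, whereas full slabs would split the silhouette and carry no
  coefficient signal. Spec-level porosity of a fixture is therefore exact.
* **Sampling**: candidate points are drawn in the *envelope* (70 % biased
  into a 0.12 m outer shell, emulating LiDAR's surface bias) and the void
  filter is applied afterwards — so under one seed the clouds of
  increasingly porous canopies are nested subsets, and porosity
  comparisons are driven by the voids rather than by sampling noise.
  Density default: 6000 points/m³ of envelope; sensor noise: isotropic
  Gaussian, $\sigma = 0.02$ m per coordinate, the scanner's stated range
  accuracy.
* **Orchard**: rows 3.5 m apart, plants 1 m apart, tree height ≈ 3.5 m
  with ±4 % variation, foliage base 0.6 m above ground (the trunk carries
  no returns), base radius 0.45 m so neighbouring crowns fuse into a tree
  wall while spilling under 5 % of any tree's points past the column
  midpoint; flat, undulating (0.1 m) or tilted (5 %) ground at 400
  points/m²; uniform noise points at a configurable rate.
* **Virtual reference instrument**: the laboratory projection measurement
  is reimplemented computationally — three-section envelope volume times
  the product of per-direction shaded silhouette fractions, rendered
  orthographically on a 2 cm grid with 48 samples per ray. Orthographic
  rays mean the divergent-light inflation of a physical point-source rig
  is absent by design; the virtual reference is unbiased.

What the generator does **not** emulate: botanically realistic branch
architecture, scan-line anisotropy and occlusion shadows of a moving
sensor, beam divergence, foliage movement, or mixed ground vegetation.
Passing tests therefore demonstrate that the implementation realizes the
method faithfully on clouds with known truth — not that the method's
accuracy on field scans equals its accuracy here.

## Numerical choices

* Delaunay predicates in scaled double precision with cavity edge-validity
  checks; degenerate insertions retry under deterministic, growing
  perturbations, so grids and other cospherical configurations are handled
  without randomness.
* Half-open binning everywhere, anchored at minimum corners; voxel centers
  on a contour edge count as inside; profile top-edge points belong to the
  last bin.
* Trough-depth comparisons carry a $10^{-9}$ m tolerance so thresholds hit
  exactly (e.g. a depth of 0.8 against a threshold of 0.8) behave as
  written rather than at the mercy of rounding.
* Zero-weight interpolation is capped at one round per partition; leftover
  zeros (no path to any non-zero weight inside the contour) are an error,
  not a silent fill.
* Exact duplicate points are removed before tetrahedralization only (they
  cannot carry volume); $d_{avg}$ keeps them.

## Problem sizes

The test suite and the acceptance script run on clouds of roughly 2 000 to
125 000 points: 2 000-point sphere oracles, 64 000-point solid-cube
saturation checks, 6 000–11 000-point single canopies, a 12-tree simulated
experiment, and one full 15-tree orchard scene (~84 000 points after
preprocessing). These sizes give the statistical headroom the assertions
need (coefficient saturation, ordering margins, segmentation purity) while
keeping a full run in the tens of seconds on one core.

## Known limitations

* The coefficient sees porosity through the projections. Interior voids
  that no view can see through (fully occluded by material along all three
  axes) are partially discounted at moderate density and invisible in the
  saturated limit — the same occlusion limitation the physical three-view
  instrument has. The effective volume is accordingly an upper bound that
  tightens with viewable porosity.
* A canopy whose silhouette splits into disjoint parts (e.g. a full
  horizontal gap) is treated as two silhouettes; the gap between them is
  not canopy and not porosity.
* The global dynamic $\alpha$ follows the baseline-plus-growth scheme; a
  per-region locally varying $\alpha$ is a possible extension, not
  implemented.
* `method = "csf"` ground filtering is an interface to an external
  cloth-simulation backend; the shipped grid filter is the default and is
  what the tests exercise.
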