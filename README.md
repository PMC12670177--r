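# canopyEV

Estimating fruit-tree canopy volume from LiDAR point clouds is a standard
step in precision orchard management — spray dosing, yield estimation, and
pruning decisions all key off it. The classical estimators (convex hulls,
alpha-shapes, slice-wise variants, voxel counting) all measure the *envelope*
spanned by the points. A real canopy, however, is mostly air: the gaps
between branches and leaves (porosity) are inside that envelope, so envelope
methods systematically overestimate the amount of actual canopy.

`canopyEV` computes the canopy **effective volume**: the envelope volume
discounted by a porosity-sensitive coefficient estimated from the cloud
itself,

```
V_e = V_m · EVC,        EVC = EC_xoy · EC_xoz · EC_yoz
```

where

* **V_m** is the volume of a closed surface mesh reconstructed with a
  density-adaptive alpha-shape: the baseline radius is `α = k · d_avg`
  (`k = 5`, `d_avg` = mean nearest-neighbour distance of the cloud) and α
  grows in steps of `0.5 · d_avg` until the alpha-shape boundary is a
  closed, edge-manifold surface. The volume is the divergence-theorem sum
  `|Σ V₀ · (V₁ × V₂)| / 6` over the oriented boundary triangles.
* **EC_p** (one per orthogonal projection plane) is a thickness-weighted
  occupancy ratio: the projected cloud is voxelized at voxel size
  `VS = d_avg`, bounded by a 2D alpha-shape outer contour, partitioned into
  `5 × 5`-voxel blocks each weighted by the local canopy thickness
  `W = max − min` of the dropped coordinate (zero-weight blocks are filled
  by iterative eight-neighbour averaging), and
  `EC = Σ W·n_ev / Σ W·n_av` — the fraction of in-contour voxels that
  actually contain points, weighted by thickness. Through-gaps and sparse
  interior regions pull EC below 1; multiplying the three planes mimics a
  physical three-view shadow-projection measurement.

The package also provides the surrounding pipeline: point-cloud I/O
(PLY/PCD/LAS/XYZ), radius-outlier denoising, RANSAC ground leveling, ground
filtering, orchard row segmentation (Gaussian KDE of Y), tree-wall column
segmentation (height-trough screening), three reference estimators
(alpha-shape by slices, convex hull by slices, voxel counting) with volume
reduction rates, and a synthetic tall-spindle orchard generator with
closed-form ground-truth volumes for validation.

## Worked example

```r
library(canopyEV)

# a synthetic tall-spindle canopy, 30% internal porosity, known truth
can  <- makeSpindleCanopy(porosity = spindlePorosity(0.3), seed = 3)
can
#> SyntheticCanopy: 7818 points (7818 canopy, 0 ground, 0 noise)
#>   truth: envelope 1.9058 m^3, solid 1.3341 m^3, porosity 0.300

mesh <- reconstructCanopy(can@cloud)
mesh
#> CanopyMesh: 7818 vertices, 2356 triangles | alpha = 0.1660 m (1 iterations)
#>   volume = 1.8159 m^3

effectiveVolume(can@cloud, mesh)
#> Canopy effective volume
#>   Vm  = 1.8159 m^3
#>   EC  = xoy 0.9824 | xoz 0.8911 | yoz 0.9429
#>   EVC = 0.8254
#>   Ve  = 1.4989 m^3
```

The envelope mesh (1.816 m³) overshoots the true material volume
(1.334 m³) by 36%; the effective volume (1.499 m³) cuts that error to 12%.
The reference estimators on the same cloud illustrate the usual ordering of
envelope methods:

```r
volumeCHBS(can@cloud)$volume   # 2.70  convex hull by slices
volumeVB(can@cloud)$volume     # 2.28  voxel counting
volumeASBS(can@cloud)$volume   # 2.03  alpha-shape by slices
```

so `V_CHBS > V_VB > V_ASBS > V_e`, with `V_e` the only estimate that
discounts interior porosity.

For whole scenes, `runPipeline()` chains preprocessing, row/column
segmentation, per-column reconstruction, the effective-volume computation
and the baselines into one JSON-able report; `inst/cli/canopy_ev.R` exposes
each stage as a shell subcommand
(`preprocess`, `segment`, `reconstruct`, `evc`, `compare`, `simulate`, `run`).

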