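Package: canopyEV
Title: Effective Volume of Fruit-Tree Canopies from LiDAR Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the effective volume of fruit-tree canopies from LiDAR
    point clouds. The canopy envelope is reconstructed with a density-adaptive
    alpha-shape (baseline alpha from the mean nearest-neighbour distance, grown
    iteratively until the mesh closes) and its volume is discounted by an
    effective volume coefficient derived from voxelized orthogonal projections,
    so that internal porosity between branches and leaves is excluded from the
    estimate. Includes orchard preprocessing (radius outlier removal, RANSAC
    ground leveling, ground filtering), row and column segmentation of
    tall-spindle tree walls, three reference volume estimators (alpha-shape by
    slices, convex hull by slices, voxel counting), point-cloud readers and
    writers for PLY, PCD, LAS and XYZ, and a synthetic orchard generator with
    analytic ground-truth volumes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RANN,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
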