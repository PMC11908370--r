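Package: mlbrainnet
Title: Node-Reconfiguring Multilayer Networks of Brain Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and analysis of node-reconfiguring multilayer
    networks from voxel-level functional imaging data. Regions of interest
    (ROIs) are re-optimized for functional homogeneity inside each time
    window using greedy region-growing clustering (weighted mean consistency
    or minimum correlation priorities, with ReHo-based seeding and
    percentile thresholding) or normalized-cut spectral clustering; static
    label-volume atlases and random region-grown parcels are supported as
    references. Time windows form the layers of a multilayer network with
    Pearson-correlation intralayer edges and Jaccard-overlap interlayer
    edges. Analytics include spatial consistency, regional homogeneity,
    within/between-ROI correlation distributions, ROI stability scores and
    trajectories, binned interaction curves, and consistency carryover
    between consecutive windows. A synthetic voxel time-series generator
    with planted, reconfiguring parcellations supports validation without
    any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
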