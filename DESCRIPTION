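Package: vesseltrace
Title: Sequential Tracing and Segmentation of Vascular Structures in 3D Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs connected vascular segmentations and surface meshes from
    3D medical-style image volumes by sequential local segmentation. Starting
    from a single seed point with a direction and radius estimate, the tracer
    extracts radius-scaled cubic subvolumes, segments them with a pluggable
    local segmenter, converts each local segmentation to a surface, extracts
    centerlines by gradient descent on a fast-marching arrival-time field,
    steps along the vessel, queues bifurcations by radius, and fuses all local
    predictions into a single global probability map with Gaussian weighting.
    Includes a synthetic tubular phantom generator with exact ground-truth
    masks and centerlines, the centerline-based stochastic patch sampler and
    Dice/cross-entropy loss terms used to train local segmenters, and
    evaluation metrics (Dice, Hausdorff distance, centerline overlap) with a
    six-radius centerline evaluation mask.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml,
    optparse
Config/testthat/edition: 3
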