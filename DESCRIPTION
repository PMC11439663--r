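Package: pscdnet
Title: Functional Brain-Network and Imaging-Biomarker Analysis of Delayed
    Post-Stroke Cognitive Decline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for nested case-control studies of delayed
    post-stroke cognitive decline. Builds functional connectivity matrices
    from region-level BOLD time series, computes conventional graph
    attributes (characteristic path length, global efficiency, modularity,
    clustering coefficient, transitivity) at proportional density thresholds
    with degree-preserving rewiring-null normalization, estimates system
    segregation of canonical resting-state networks from Fisher
    z-transformed connectivity, quantifies amyloid-PET standardized uptake
    value ratios against a cerebellar reference and white-matter
    hyperintensity lesion burden on a common voxel grid, classifies
    decliners from MMSE trajectories with age/NIHSS control matching, and
    runs the group-difference and brain-cognition association statistics
    including a voxel-wise logistic model. A synthetic cohort generator
    emulates every input (modular block-correlation BOLD, structured PET
    and lesion volumes, coupled MMSE trajectories) so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
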