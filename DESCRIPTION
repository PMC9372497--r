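Package: netfuse
Title: Fusion of Multi-Atlas Cognitive Networks by Graph Discriminability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesizes a combined cognitive network from several
    atlas-defined instances of the same network (e.g. the fronto-parietal
    network as delineated by different brain parcellations), builds
    per-condition, per-subject functional-connectivity matrices from ROI
    time series, thresholds them into binary graphs by false-discovery-rate
    control over edge p-values, and selects the atlas instance whose graph
    properties best discriminate cognitive states. Remaining ROIs are
    ranked by the discriminability of their nodal degree centrality and
    greedily fused, prefix by prefix, into a fused network with minimal
    discriminability p-value. Includes a planted-subnetwork synthetic data
    generator so the whole pipeline can be exercised and calibrated
    without access to fMRI recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'atlas.R'
    'connectivity.R'
    'nifti.R'
    'graph-metrics.R'
    'stats-tests.R'
    'fusion.R'
    'report.R'
    'synthetic.R'
    'netfuse-package.R'
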