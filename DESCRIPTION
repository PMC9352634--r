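Package: smartline
Title: Design and Processing of Smart Line Scanning Trajectories for
    Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for smart line scanning (SLS) two-photon calcium
    imaging. Builds minimal-length scan trajectories through segmented
    regions of interest (genetic-algorithm solution of the centroid
    travelling-salesman problem plus greedy intra-ROI paths, optional
    surround regions and a reference box), and processes the resulting
    line recordings: large-artefact detection from the autoregressive
    consistency of the leading principal component, rank-1 background
    subtraction, line-by-line motion correction (reference-box
    registration or SNR-based pixel reassignment), local and global
    neuropil decontamination, trace extraction, autoregressive
    deconvolution and quality metrics. A synthetic-session simulator
    provides ground truth for every stage, and raster-scan utilities
    cover registration, projections, SNR-driven pixel selection,
    longitudinal segmentation alignment and dF/F0 normalisation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
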