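Package: lungmetmap
Title: Metastasis Colonization Heatmaps from Chest CT Vessel Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts a 3D chest CT volume into an L1-normalized probability
    heatmap of likely lung-metastasis colonization sites. The pipeline extracts
    a cylinder-approximated blood-vessel flow graph and a healthy-tissue lung
    mask from the image, then drives a three-layer biophysical model (Gompertz
    primary-tumor growth to vessel contact, bloodstream transport with
    exponential decay and an extinction threshold, and saturating tissue
    colonization) over a sampled spatial grid. Includes a synthetic phantom
    generator with exact ground truth, soft/hard overlap classifiers for
    validation, and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    igraph,
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
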