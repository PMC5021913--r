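Package: snclust
Title: Select-and-Cluster Extraction of Functional ROIs and Networks from fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven extraction of spatially compact, functionally
    homogeneous regions of interest (ROIs) from 4D fMRI time series and
    assembly of the ROIs into functional connectivity networks. The pipeline
    selects cortical voxels with significant pairwise temporal correlation by
    a two-scale (resel-level, then acquisition-level) correlation analysis,
    builds a low-dimensional functional feature space by singular value
    decomposition with MDL/AIC model-order selection, groups voxels by
    Support Vector Clustering with a composed spatiofunctional Gaussian
    kernel, and extracts seed-conditioned networks of mutually correlated
    ROIs by maximal-clique analysis. Includes generators for synthetic
    benchmark data (hybrid activation slices and 3D block-design network
    phantoms) and external cluster-validation metrics (weighted Jaccard,
    Fowlkes-Mallows with a random-labelling null).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    optparse
Config/testthat/edition: 3
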