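Package: dualtrace
Title: Dual-Ensemble Brain Activity Mapping and Functional Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for mapping two immediate-early-gene
    ensembles and their overlap across the mouse brain. Provides
    morphology-specific 3D segmentation of punctate (c-Fos-like) and
    soma-plus-process (eYFP-like) staining in confocal z-stacks,
    object-based colocalization with percent-volume filtering, a
    slice/mouse/experiment data model with thin-plate-spline registration
    to 2D atlas plates, region-volume normalization to cells per cubic
    millimetre, and downstream network statistics: Pearson correlation
    matrices with asymptotic p-values, thresholded functional networks,
    node centralities, permutation tests of group correlation differences,
    Kolmogorov-Smirnov comparison of regional correlation distributions,
    and leading-eigenvector community detection. A synthetic-phantom
    fixtures module generates ground-truth image stacks, toy atlas plates
    and correlated regional count data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    igraph,
    jsonlite,
    rlang,
    yaml,
    tiff,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Network, GraphAndNetwork, Visualization
RoxygenNote: 7.3.3
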