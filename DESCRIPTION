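Package: wiregrow
Title: Generative Network Models of Spatially Embedded Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the growth of spatially embedded binary brain
    networks under an economic cost-value trade-off, in which the
    probability of wiring two unconnected regions is proportional to a
    power of their Euclidean distance multiplied by a power of a
    topological value term (homophily, clustering or degree based).
    Provides tools to build binary networks from weighted streamline-count
    connectomes (consensus masking, absolute and density-controlled
    thresholding, distance-binned group consensus networks), a full set of
    binary graph measures including normalized rich-club detection against
    degree-preserving nulls, maximum-Kolmogorov-Smirnov energy fitting of
    wiring parameters over grids, topological fingerprints, and group
    growth experiments that track connection classes and lengths across
    generative time. Includes a synthetic-cohort generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
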