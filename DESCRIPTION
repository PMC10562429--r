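Package: gliascope
Title: Quantification of Microglial Morphology, Microtubule Dynamics and
    Intensity Distributions from Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-quantification toolkit for measuring microglial
    reactivity. Segments individual microglia from DAB-stained tissue
    sections (seeded watershed grown from area-thresholded soma seeds) and
    from CellMask-stained cultures (h-maxima seed dynamics), computes
    per-cell morphometric descriptors (ramification index, inscribed
    radius, Feret and geodesic diameters), tracks fluorescent microtubule
    plus-tip comets with LAP linking and gap closing and classifies their
    radial direction relative to the centrosome, and measures spatial
    intensity statistics (centrosome enrichment ratio, radius enclosing
    80% of cumulative integrated density). A synthetic phantom generator
    produces ground-truthed images and movies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
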