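Package: rootarch
Title: Automatic Extraction of Plant Root System Architectures from Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automatic pipeline for recovering plant root system
    architectures (RSA) from 2D images of seedlings grown on germination paper
    or transparent plates. A compact multi-task encoder-decoder convolutional
    network (single-stack hourglass core, implemented with native im2col/GEMM
    kernels) segments first- and second-order roots and regresses Gaussian
    heat maps for seeds and root tips. Discrete features are extracted by
    non-maximal suppression with spatial deduplication, optionally after dense
    CRF refinement of the segmentation, and the full architecture is
    reconstructed by A* and Dijkstra searches over distance-transform-weighted
    pixel graphs. Extracted roots are smoothed with tension-0.5 cardinal
    splines, written to standard RSML, and quantified as per-plant phenotypic
    traits (depth, width, convex hull area, centroid depth, counts, lengths).
    A procedural generator of fibrous and taproot synthetic root images makes
    the entire pipeline testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    xml2,
    png,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
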