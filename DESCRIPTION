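Package: beetrack
Title: Tracking Multiple Unmarked Honeybees on a Flat Laboratory Arena
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identity-preserving tracking of multiple dark, unmarked animals
    (honeybees) walking on a bright flat arena, from grayscale image
    sequences. Frames are segmented by a per-pixel maximum background model,
    subtraction and fixed-threshold binarization; individuals are identified
    through merges and splits by combining a calibrated single-bee size range
    with spatiotemporal region overlap, linear-motion prediction and
    translational regional matching. The package also provides a
    swarm-algorithm-inspired synthetic arena simulator with exact ground
    truth, scripted two- and three-bee interaction fixtures, encounter
    detection and classification (crossing, touching, passing, overlapping,
    waiting, multiple), and trajectory evaluation via fragmentation (TFF) and
    completeness (TCF) factors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
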