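Package: wormtrails
Title: Identity-Preserving Track Stitching for Multi-Worm Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts the thousands of short, fragmented blob tracks produced
    by real-time multi-animal segmentation (Multi-Worm-Tracker-style output)
    into long per-animal trails. Tracks are organised as nodes of a directed
    acyclic network whose arcs encode physically possible succession; a fixed
    sequence of heuristic corrections (pixel-overlap collision untangling,
    missing-arc inference under time/distance caps, pruning of sub-second
    orphan fragments, and consolidation of split-rejoin motifs) simplifies
    the network until each animal is a single isolated chain. Includes a
    synthetic recording simulator with ground-truth identities for
    validation, scoring of stitched trails against truth, and downstream
    centroid-speed and activity-classification analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
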