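Package: nephtrack
Title: Automated 3D Tracking of Nephron Tubules Through Serial Histological Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing individual kidney tubules (nephrons) in three
    dimensions from stacks of serial histological section images. Each slice is
    preprocessed into a binary image isolating tubule lumens, with filter parameters
    varying by depth along a sigmoid schedule anchored at the cortico-medullary
    transition zone. Lumen cross sections are abstracted into nodes carrying
    dimensionless shape factors and 24-point centroidal shape profiles. A graph-based
    tracker grows parent/child links from a seed point through vertical and
    horizontal edges, guarded by local translational registration, controlled slice
    skipping, a three-rule validation base, and an optional multiclass
    machine-learned move validator (one-vs-all neural network and RBF-kernel support
    vector machine over a 66-feature move descriptor). A synthetic tubule-phantom
    generator with known ground truth makes every stage testable without original
    animal datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
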