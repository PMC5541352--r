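Package: rfindex
Title: Multi-Lattice Indexing of Snapshot Diffraction Images in
    Rodrigues-Frank Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Indexes serial-crystallography snapshot diffraction images that
    contain Bragg spots from many simultaneously exposed crystals. Observed
    spots are mapped onto the Ewald sphere, every candidate (spot, reflection)
    pairing defines a geodesic of compatible orientations that is a straight
    line in Rodrigues-Frank space, and geodesics are ray-traced through a
    four-chart voxelization of orientation space; voxels visited by many
    geodesics seed candidate orientations that are matched, refined by
    orthogonal-Procrustes fitting with outlier trimming, and accepted by
    match-count, completeness and uniqueness criteria. Includes a synthetic
    multi-crystal snapshot generator with ground-truth orientations, Poisson
    crystal-arrival statistics, and symmetry-reduced misorientation analysis
    for scoring results and studying crystal agglomerates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
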