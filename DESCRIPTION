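Package: shapemem
Title: Shape-Memory Model of Asymmetric Neural Progenitor Division
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates how the shape of a mitotic neural progenitor biases
    the fates of its daughters. A three-dimensional cellular Potts model
    drives mitotic rounding and division of a single voxelized cell, with
    membrane-bound particle agents (cortical force generators that set the
    division axis, and Delta ligand molecules that seed a Delta-Notch
    lateral-inhibition switch between the daughters). The package also
    provides the voxel-based shape and protein-localization metrics used to
    connect cellular eccentricity to fate (inertia-tensor principal axes,
    asymmetric-elongation index, fate-axis angle, intensity-centroid
    displacement), a synthetic-shape generator for controlled-eccentricity
    fixtures and confocal-like stacks, and ensemble drivers with chi-squared
    statistics and physical-unit calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
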