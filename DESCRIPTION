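Package: resectfit
Title: Best-Match Surface Analysis of Tibial Bone Resections Against
    Implant Tray Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well a resected unicompartmental-knee tibial bone
    specimen matches the tibial implant component it was cut for. Reads
    cone-beam CT volumes (NIfTI, MetaImage, single-frame DICOM series) and
    implant tray meshes (STL, PLY, OBJ), segments the specimen by grey-value
    thresholding, extracts a triangle surface by marching tetrahedra,
    rigidly aligns it onto the tray with trimmed iterative-closest-point
    registration, maps per-vertex signed surface distances with an
    eight-band colour binning, splits the matched surface into the four
    anteromedial/posteromedial by medial/central compartments and reports
    per-compartment maximal bone elevation, total mismatch and the
    central-to-medial surplus quotient, and scores sclerosis of the most
    distal cut slice with an upper-third grey-value cut-off. Ships a
    synthetic phantom generator with analytic ground truth and a cohort
    layer with Welch group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
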