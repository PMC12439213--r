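Package: contourqa
Title: Geometric, Dosimetric and Timing Evaluation of Radiotherapy Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality assessment of organ-at-risk (OAR) delineations
    in radiotherapy planning. Computes the standard geometric agreement
    metrics between a test contour and a ground-truth reference (mean surface
    distance, Dice similarity coefficient, Hausdorff distance, volume
    difference and centre-of-mass difference) on spacing-aware voxel grids
    using an exact anisotropic Euclidean distance transform, extracts DVH
    dose summaries (Dmin/Dmax/Dmean/Dmedian) from dose grids or treatment
    planning system exports, and aggregates multi-observer cohorts into
    percentile summaries, inter-observer variability and contouring
    time-saving statistics. Includes a fully synthetic digital-phantom cohort
    generator (parametric head-and-neck organ analogues, controlled observer
    noise, dose field and timing distributions) so the complete pipeline can
    be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
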