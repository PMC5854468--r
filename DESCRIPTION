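Package: curvtrack
Title: Curvature-Guided Filament Orientation Energetics and Trajectory
    Statistics for Bacterial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how membrane-bound, intrinsically curved
    cytoskeletal filaments (such as bacterial MreB) orient on cell surfaces,
    and to quantify the alignment of their motion with cell geometry. The
    package implements an elastic-beam/Helfrich energy model giving the
    binding-angle energy landscape of a curved filament on a surface of
    given principal curvatures, a trajectory-statistics pipeline (orthogonal
    line fits, mean-squared-displacement motion classification, directional
    filters, angles to the cell midline, pairwise angle and dot-product
    statistics), cell-contour geometry (3-point sidewall curvature, width
    profiles and midlines, principal-curvature ratios, tangent-angle
    correlation, area-based doubling times), and a synthetic-data module
    that generates contours, trajectories and random-angle null fields with
    the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
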