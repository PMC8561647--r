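Package: tmsfocal
Title: Focality-Optimized TMS Coil Placement on Triangulated Head Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for solving the transcranial magnetic stimulation (TMS)
    inverse problem: given a multi-shell triangulated head model, a coil
    modelled as a magnetic-dipole cloud, and a cortical target point, find
    the six-parameter coil pose (position plus pitch/roll/yaw) that
    minimizes the average absolute deviation (AAD) of the suprathreshold
    electric field from the target on an intracortical observation surface.
    Includes a direct boundary-element forward solver formulated in terms of
    induced surface charge density with a one-time operator factorization, a
    closed-form spherical-conductor oracle, synthetic nested-sphere and
    gyrus head phantoms, sulcus-aligned initial coil placement, sequential
    coordinate-descent pose search with a perturbation-based stability
    (defocalization) correction, and focality/somatotopy metrics (AAD, ARD,
    field loss, peak deviation, focality improvement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
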