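Package: atriamesh
Title: Left-Atrial Surface Reconstruction, Registration and Conduction-Field
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-modal pipeline for three-dimensional left-atrial geometry.
    Reconstructs closed endocardial surface meshes from sparse stacks of 2D
    MRI contours by ruled-surface initialisation followed by iterative
    attractor-based thin-plate-spline deformation with Laplacian smoothing,
    subdivision and quadric decimation; reconstructs meshes from intra-chamber
    ultrasound style point clouds by a Poisson indicator-function solver;
    co-registers reconstructions with generalized ICP (plane-to-plane);
    computes geometric and clinical comparison metrics (surface distance,
    enclosed volume, surface area, equivalent wall thickness); transfers and
    analyses per-vertex conduction fields (conduction velocity, pathological
    conduction pattern frequencies) including proximity to adjacent thoracic
    structures and contact statistics; and generates synthetic phantoms
    (contour stacks, point clouds, vertex fields) so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    tools,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
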