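Package: stentforge
Title: Semi-Automated Design of 3D-Printable Mouth-Opening
    Tongue-Depressing Oral Radiation Stents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts a pair of articulated maxilla and mandible surface
    meshes (millimetre STL) plus dental landmarks into a printable
    mouth-opening, tongue-depressing (MOTD) oral radiation stent via a
    deterministic nine-step workflow: PCA occlusal-plane fitting, an
    expanded convex-hull shell carrying a carved dental impression,
    landmark-driven part decomposition, tongue-space subtraction and
    feature-protected smoothing.  Ships a triangle-mesh engine (BSP-tree
    constructive solid geometry with a voxel-remeshing fallback, watertight
    repair, quickhull, STL input/output, a ray-cast voxel volume oracle), a
    deterministic synthetic dental-anatomy generator covering edentulous,
    hypodontia, normal-occlusion and class III presets, and evaluation
    metrics (stent volume, plate thickness, plane placement,
    between-group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
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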