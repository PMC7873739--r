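Package: sacronav
Title: QCT-Based Finite-Element Planning and Drill-Guide Accuracy Auditing
    for Sacral Pedicle Screw Revision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open re-implementation of a combined computer-aided-design and
    finite-element workflow for revision sacral pedicle screw placement around
    a retained broken screw. From a calibrated quantitative-CT-like volume the
    package builds a patient-specific heterogeneous bone model (phantom-based
    Hounsfield-unit to density calibration, density to elastic-modulus
    mapping), meshes bone-plus-screw assemblies with quadratic tetrahedra,
    compares pull-out stiffness of candidate screw trajectories under tensile
    load, generates a drill-guide template geometry, and audits realized
    drilling accuracy against the virtual plan (rigid registration, cylinder
    axis fitting, 3D angles, Gertzbein-Robbins grading). A synthetic phantom
    generator provides fully reproducible test volumes with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
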