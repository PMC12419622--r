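Package: arcmetrics
Title: MLC Aperture Conformity and Dosimetric Index Evaluation for Arc
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("arcmetrics", "developers", email = "arcmetrics@example.org",
           role = c("aut", "cre"))
Description: Audits arc-radiotherapy (VMAT and dynamic conformal arc)
    treatment plans against a zero-margin conformal reference. Builds
    voxel-mask target structures with anisotropic margin expansion,
    projects them into the beam's-eye view at each control point of an
    arc, fits per-leaf-pair reference multileaf-collimator (MLC)
    apertures, and scores plans with an intrusion-only ratio of area
    difference. Also computes a standard dosimetric index panel on 3D
    dose grids: conformation number, conformality index, homogeneity
    index with isodose-line normalization, the R50% and D2cm gradient
    metrics, and dose-volume-histogram queries. Includes minimal DICOM
    RT-PLAN/RT-DOSE/RT-STRUCT readers and writers, plain-text grid and
    plan formats, a synthetic phantom/plan/dose generator with
    closed-form answers for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
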