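Package: jsmap
Title: 3-D Joint Space Mapping from CT-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertex-wise measurement of joint space width (JSW) across
    articular bone surfaces from isotropic CT-like volumes. Casts the
    shadow of an opposing bone onto a reference surface mesh to delimit
    articular patches, fits a blurred two-edge intensity-profile model
    along surface normals for sub-voxel JSW estimation, registers
    per-subject maps rigidly to a template, and quantifies inter-operator
    reproducibility and test-retest repeatability as vertex-wise
    Bland-Altman maps together with permutation-based statistical
    parametric mapping of JSW against joint angulation. Includes a
    synthetic articulating joint-phantom generator with known gap fields
    for validation, emulating weight-bearing CT acquisitions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    igraph,
    minpack.lm,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
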