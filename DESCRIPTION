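Package: osseoimpact
Title: Impact Damage Simulation for Bone Around a Dental Implant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating transient impact damage to the bone
    surrounding an osseointegrated dental implant. Provides a parametric
    conformal tetrahedral mesh generator for an implant-in-bone block
    (cortical shell over cancellous bone), one-dimensional stress-wave
    analysis of split Hopkinson pressure bar (SHPB) gauge records with a
    forward generator of synthetic records for elastic-perfectly-plastic
    specimens, an explicit central-difference elastodynamics solver on
    linear tetrahedra with lumped mass and rigid frictionless spherical
    impactor contact, a von Mises yield / element-deletion failure rule for
    bone, and a pipeline that drives a load magnitude x direction matrix,
    probes stress-time curves, runs mesh-convergence studies and reports
    per-region damage counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
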