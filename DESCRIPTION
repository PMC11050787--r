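Package: ligsim
Title: Virtual-Ligament Knee Joint Simulator Emulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static emulation of a six degree-of-freedom joint simulator
    testing total knee replacements with a virtual ligament model. Implements
    the Wismans/Blankevoort quadratic-to-linear ligament force law, a
    calibrated load-displacement model of the unsensed structural compliance of
    the upper actuator, Grood-Suntay style joint kinematics, elastic-foundation
    implant contact with regularized Coulomb friction, a rigid ground-truth
    knee equilibrium model, and experiment drivers for passive flexion,
    preload-compensation comparison and virtual PCL resection sweeps. All
    fixtures (implant surface meshes, a 14-bundle ligament apparatus,
    compliance anchors) are generated synthetically.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
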