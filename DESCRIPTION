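Package: eadsim
Title: Stochastic Calcium-Spark Modeling of EAD Alternans in Cardiac Cells and Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A multiscale model of arrhythmogenesis driven by early
    afterdepolarizations (EADs). A ventricular cell model couples stochastic
    recruitment of calcium sparks at junctional ryanodine-receptor clusters to
    a two-population Markov L-type calcium channel and rabbit ventricular
    ionic currents; its deterministic limit, a 2D monodomain tissue simulator,
    action-potential-duration (APD) analysis, and a nonlinear restitution-map
    toolkit (spline fitting, fixed points, subcritical pitchfork
    classification, conduction-block phase diagrams) reproduce EAD alternans,
    bistability, and conduction block under periodic pacing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
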