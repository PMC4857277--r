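Package: plaqrecon
Title: Necrotic Core Backside Reconstruction and Peak Cap Stress in
    Coronary Plaque Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the light-obscured backside of a
    coronary plaque necrotic core from front-side contours, as seen by
    intravascular optical imaging, and for computing peak cap stress by
    2D plane-strain finite-element analysis with neo-Hookean materials.
    Includes plaque morphometry from nested wall contours (cap thickness,
    intima-media thickness, necrotic core angle), group-averaged and
    plaque-specific (generalized estimating equation) relative necrotic
    core thickness models, a synthetic plaque cohort generator calibrated
    to published cohort statistics, Dice-type geometry scoring, backward
    incremental prestress, and an end-to-end comparison pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    polyclip,
    sp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
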