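Package: ovtr
Title: Virtual Torsional Rigidity and Callus Morphometry for Ovine
    Osteotomy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative evaluation chain for plate-stabilised sheep tibia
    osteotomy experiments: phantom-based micro-CT densitometry calibration,
    fracture-callus segmentation and morphometry (volume, mineral density),
    image-based voxel finite-element simulation of torsion tests yielding a
    virtual torsional rigidity (VTR), torque-rotation trace analysis for
    biomechanical stiffness and rigidity with contralateral normalisation,
    histomorphometric tissue-fraction quantification, and the two-arm
    group-comparison statistics (pooled t, Levene, Lilliefors-corrected
    Kolmogorov-Smirnov, exact Mann-Whitney U, Cohen's d). A synthetic
    micro-CT / torsion-trace generator with analytic ground truth drives
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
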