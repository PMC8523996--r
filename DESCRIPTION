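Package: dynfdopa
Title: Kinetic Modeling and Model Comparison for Dynamic 18F-FDOPA PET of Gliomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing 30-minute dynamic 18F-FDOPA PET
    time-activity curves (TACs) of newly diagnosed gliomas. Implements an
    image-derived input function with spill-out, hematocrit and plasma
    metabolite-fraction corrections; semiquantitative TAC modeling
    (time-to-peak, late slope and vascularization-function fit parameters,
    with or without a healthy-brain reference region); Logan graphical
    analysis with plasma input or reference region; a reversible
    two-tissue compartmental model with analytic forward solution and
    weighted nonlinear least-squares estimation; a synthetic cohort
    generator with IDH-genotype-dependent kinetics; and the diagnostic
    model-comparison statistics (per-parameter ROC analyses, stepwise-AIC
    multivariable logistic models, paired one-sided DeLong superiority
    tests and Benjamini-Hochberg adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
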