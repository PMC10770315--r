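Package: viscoclot
Title: Control-Oriented Viscoelastic Models of Blood Clot Strength
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Phenomenological transfer-function models of thromboelastography
    (TEG) clot-strength traces. Simulates plasma and whole-blood viscoelastic
    curves from delayed second-order models, extracts the clinical TEG
    parameters (R, K, alpha angle, MA, Ly30), fits model parameters to
    measured traces by bounded least squares with AIC model-order selection,
    learns sparse linear maps from coagulation-factor panels to model
    parameters via orthogonal matching pursuit with k-fold cross-validation,
    interconverts the Functional Fibrinogen, Citrated Native, Platelet
    Mapping and Rapid TEG assay variants, and relates the models to the
    generalized Maxwell description of viscoelasticity. Includes a seeded
    synthetic-cohort generator so the full pipeline can be exercised without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
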