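Package: suprafit
Title: Coupled Solution Equilibria, Titration Forward Models and
    Cooperativity Analysis for Ion-Pair Binding Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative thermodynamic description of
    host-guest ion-pair binding in nonaqueous solvents.  Provides a general
    speciation solver for simultaneous solution equilibria (complexation,
    ion pairing, anion dimerization) with optional solid phases handled by
    an active-set saturation scheme; closed-form salt solubility and
    precipitation models with their fitting procedures; forward models for
    potentiometric (ion-selective electrode), conductometric, calorimetric
    (ITC), UV spectrophotometric and fast-exchange NMR titrations; global
    nonlinear fitting under a three-level binding-model ladder with
    cooperativity factors; synthetic-data generators with known ground
    truth for every supported experiment; and classification of labelled
    3-D structure frames into discrete coordination matrices with
    PCA-based representative selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
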