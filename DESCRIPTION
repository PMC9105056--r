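Package: batdx
Title: Basophil Activation Test Analytics for Lipid Transfer Protein Allergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for basophil activation test (BAT) data in
    lipid transfer protein (LTP) allergy, built around the peach allergen
    Pru p 3 and its peanut homologue Ara h 9.  Provides per-subject
    dose-response analytics (four-parameter log-logistic fits, CD-sens
    basophil allergen threshold sensitivity, area under the activation
    curve, nonresponder flagging), ROC-based diagnostic cut-off derivation
    with sensitivity/specificity/PPV/NPV, a consecutive-concentration BAT
    positivity rule, cohort summary statistics and group comparisons,
    principal component analysis of subject-level features, and a seeded
    synthetic-cohort generator emulating flow-cytometry summary data so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
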