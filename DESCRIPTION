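Package: anfiscad
Title: ANFIS-Based Computer-Aided Diagnosis of Thyroid Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differentiates benign from malignant thyroid nodules from coded
    sonographic signs with a first-order Takagi-Sugeno fuzzy inference system
    (ANFIS) trained by a real-coded genetic algorithm, with backpropagation and
    hybrid least-squares/gradient trainers as comparators. Rule premises are
    initialized by fuzzy c-means clustering. Includes the accuracy/sensitivity/
    specificity evaluation protocol over holdout and k-fold splits, a Gini
    decision-tree module that ranks sonographic signs and exports prepruned
    risk-stratification guideline trees, and a seeded generator of synthetic
    nodule tables following the 27-sign coding schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
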