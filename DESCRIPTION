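Package: concordROC
Title: Concordant Partial AUC and Partial c Statistic for ROC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating classifiers and diagnostic tests on
    imbalanced data using partial regions of the ROC plot. Implements the
    concordant partial AUC (the average of the vertical and horizontal
    partial areas over a partial curve), the partial c statistic computed
    from weighted stripes of the pairwise concordance matrix, and the
    classical measures they generalize: the trapezoidal AUC, the c
    statistic, vertical and horizontal partial AUCs, normalized and
    McClish-standardized partial areas, and average precision in both
    class orientations. Includes the concordance matrix whose border
    reproduces the empirical ROC curve, endpoint-resolution rules that
    turn false-positive-rate boundaries into on-curve partial ranges, a
    binormal score simulator, staircase fixtures, delimited score-table
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
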