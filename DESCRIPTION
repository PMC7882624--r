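Package: uromarker
Title: Label-Free Urinary Proteomics Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for label-free LC-MS urinary proteomics biomarker
    discovery in multi-group case/control designs. Implements Top-3
    peptide-to-protein quantification with summed-intensity normalization,
    differential-expression calling for zero-inflated abundance matrices
    (including a group-specific zero-pattern rule), cross-contrast overlap of
    differentially expressed proteins, single- and two-marker diagnostic
    evaluation by ROC analysis with a closest-to-(0,1) Euclidean cutpoint
    index, DeLong confidence intervals, logistic-regression composite
    markers, Fisher's exact over-representation analysis with a menu of
    multiplicity corrections, and a fully parameterised four-group study
    simulator with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
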