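Package: rppasig
Title: Reverse-Phase Protein Array Signaling Analysis for Neoadjuvant Trial Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for reverse-phase protein array (RPPA) data
    from neoadjuvant breast cancer trial cohorts. Converts triplicate spot
    intensities to total-protein-normalized endpoint values, removes array
    batch effects by receptor-subtype-balanced resampling and z-scoring,
    screens analytes for association with pathologic complete response via
    adjusted logistic likelihood-ratio tests with Benjamini-Hochberg control,
    defines signaling clusters by Pearson/complete-linkage hierarchical
    clustering, analyses distant recurrence-free survival per cluster with
    Cox models, and derives and applies a two-phosphoprotein HER2-activation
    response-predictive signature using Youden-index cut points. A synthetic
    cohort generator with known ground truth (batch effects, planted response
    effects, exponential survival) supports parameter-recovery testing of
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
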