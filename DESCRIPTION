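Package: steroidstage
Title: Staging Liver Fibrosis from the Urinary Steroid Metabolome with
    Matrix-Relevance Learning Vector Quantisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-invasive staging of non-alcoholic fatty liver disease
    (NAFLD) fibrosis from urinary steroid metabolite panels measured by
    GC-MS. Provides creatinine correction, log10 transformation and
    leakage-free standardisation of steroid concentrations, glucocorticoid
    enzyme-activity ratios (11beta-HSD1, A-ring reductase), serum
    comparator scores (APRI, FIB-4, AST/ALT, NAFLD fibrosis score, BARD),
    a from-scratch Generalised Matrix Learning Vector Quantisation (GMLVQ)
    classifier with an adaptive relevance metric whose diagonal ranks
    metabolites, repeated stratified-split ROC/AUC validation with
    percentile confidence intervals, backward panel reduction to a compact
    steroid signature, and a synthetic cohort simulator emulating the
    statistical structure of a biopsy-staged NAFLD case-control study.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
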