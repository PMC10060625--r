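Package: copsig
Title: Cuprotosis Expression Patterns and COPsig Prognostic Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and quantification of copper-induced cell death
    (cuprotosis) expression patterns in bulk tumour transcriptomes.
    Provides Monti-style consensus clustering with PAC-based selection of
    the cluster number, single-sample gene-set enrichment (ssGSEA),
    ESTIMATE-style immune/stromal scores and TMEscore, moderated
    differential expression, Kaplan-Meier/log-rank/Cox survival machinery
    with optimal-cutpoint stratification, a Boruta shadow-feature
    selector, the COPsig per-patient signature score (difference of
    signature-wise first principal components), ridge-regression drug
    response prediction trained on cell-line panels, AUCell-style
    per-cell gene-set activity with bimodal thresholding, and seeded
    synthetic-data generators so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    limma,
    Matrix,
    mclust,
    ranger,
    stats,
    survival,
    sva,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
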