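Package: senuro
Title: Urinary Biomarkers of Renal Epithelial Senescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studies linking histologic
    renal epithelial senescence (P21+/KI67- tubular cells) to urinary protein
    biomarkers such as clusterin. Provides per-cell histology quantification
    with section pooling, spike-in and creatinine normalisation of urinary
    proteomics with a Spearman/Benjamini-Hochberg biomarker screen, a radial
    transcript-enrichment statistic for subcellular-resolution spatial
    transcriptomics, derivation of sustained renal-decline endpoints with
    ROC threshold selection and Cox proportional-hazards evaluation, and a
    matched synthetic-data generator emulating biopsy, urine, spatial and
    longitudinal outcome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    car
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    knitr
Config/testthat/edition: 3
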