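Package: methylightr
Title: In-Silico Bisulfite Conversion, MethyLight Assay Validation and
    Methylation Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for probe-based quantitative methylation-specific PCR
    (MethyLight) workflows. Models bisulfite conversion of both strands of a
    genomic region into its four possible single-stranded templates, validates
    methylation-specific primer/probe designs against those templates with
    transcription-start-site-relative amplicon coordinate arithmetic, scores
    bisulfite clone sequences for CpG retention and conversion efficiency,
    converts replicate qPCR Ct tables into standardized relative copy numbers
    against a CpG-free reference gene, and calibrates relative-copy-number
    cutoffs against a gold standard with ROC curves, the Youden index, odds
    ratios and association tests. Ships seeded generators for CpG islands,
    clone sets and Ct tables so every step is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
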