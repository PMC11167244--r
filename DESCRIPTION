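Package: autolnc
Title: Discovery of DNA Methylation-Dysregulated Autophagy-Related lncRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for identifying long non-coding RNAs
    (lncRNAs) whose promoter or enhancer DNA methylation is dysregulated in
    tumors and that regulate autophagy-related genes. Combines tumor-vs-normal
    differential expression and differential methylation (M-value tests),
    site-to-region mapping with an opposite-direction anti-correlation rule,
    tumor-purity-adjusted co-expression ranking followed by weighted
    Kolmogorov-Smirnov gene-set enrichment (lncAut scoring), a signed
    lncRNA-autophagy-gene regulatory network with activator/inhibitor
    classification, connectivity-map-style drug repositioning by enrichment of
    lncRNA target sets in drug perturbation signatures, and Kaplan-Meier /
    multivariate Cox prognostic screening. Ships a synthetic multi-omics
    cohort generator with planted effects for calibration and validation.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
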