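Package: gliomics
Title: Integrated Tumor/Normal Multi-Omics Analysis for Diffuse Gliomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated, simulation-testable pipeline for tumor/normal
    multi-omics analysis of diffuse gliomas: exome depth-ratio copy-number
    segmentation with tumor-purity estimation from allelic imbalance,
    purity-adjusted somatic-variant filtering, Infinium-style methylation
    processing (beta-values, consensus k-means clustering, differential
    promoter methylation, distal-probe selection), expression quantification
    with gene-set enrichment analysis, fusion-junction filtering, and native
    implementations of the statistical primitives the pipeline uses (Fisher
    exact, Welch t, Benjamini-Hochberg, Wilcoxon rank-sum, Kaplan-Meier,
    log-rank). Seeded synthetic-data generators emulate every input class
    with known ground truth so all stages are testable without external
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    withr,
    fgsea,
    mclust,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
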