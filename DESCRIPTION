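Package: accsig
Title: Paired Tumor-Normal Expression Signatures and Exon-Level MYB
    Rearrangement Calling for Adenoid Cystic Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for salivary gland adenoid cystic carcinoma
    (ACC) transcriptomics: paired tumor-versus-normal differential expression
    with intensity and fold-change filtering and Benjamini-Hochberg FDR
    control; exon-level changepoint calling of MYB 3' rearrangement status
    from ordered exon intensities; stratification of tumors by MYB level and
    classification of signature genes into MYB-dependent and MYB-independent
    candidates using ChIP-Seq target sets; hypergeometric gene-set enrichment;
    somatic-mutation intersection; and miRNA-mRNA inverse-target integration.
    Includes a synthetic cohort generator that emulates the paired design,
    planted fold changes, a MYB-low tumor, and exon profiles with 3' intensity
    drops, so that every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    limma,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
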