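Package: acetylscape
Title: Promoter Histone-Acetylation Dynamics Coupled to Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for time-course histone-acetylation
    ChIP-seq coupled to gene expression, as used to study chromatin responses
    to mitochondrial DNA depletion. Provides input-normalized narrow peak
    calling with Benjamini-Hochberg error control, an irreproducible-discovery
    style replicate-reproducibility filter, consensus-tag merging, TSS
    metaprofiles, a length-adjusted net-enrichment (AUC) promoter score,
    peak-to-promoter assignment, temporal trajectory clustering of peak
    enrichment, differential-expression calling with equivalence (TOST) and
    treatment-rescue classification, odds-ratio association between promoter
    peak changes and differential expression, and a consensus-rule SNP caller
    from samtools mpileup text. A synthetic-data generator emulates the
    statistical structure of the study design (planted temporal peak patterns,
    expression/peak-change coupling at a chosen odds ratio, treatment rescue,
    planted variants) with a ground-truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
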