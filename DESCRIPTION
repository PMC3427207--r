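Package: regulonscan
Title: Transcription-Factor Regulon Analysis of Cross-Cohort Expression
    Differences
Version: 0.1.0
Authors@R:
    person("Regulonscan", "Developers", email = "regulonscan@example.org",
           role = c("aut", "cre"))
Description: Detects transcription factors whose own expression changes
    plausibly drive target-gene expression differences between two sample
    groups, replicated across independent expression cohorts. Provides
    permutation-calibrated false-discovery-rate control for differential
    expression, pooled-standard-deviation effect sizes, rank-based TF
    regulatory-effect tests with regulon-permutation nulls, a cross-cohort
    correlation-of-correlations statistic, conserved-motif binding-site
    prediction with dinucleotide-shuffle and open-chromatin permutation
    nulls, background-aligned tissue-specificity comparison, and category
    enrichment with resampling-based FDR. A seeded synthetic-data module
    generates inputs with the statistical structure the analysis assumes,
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
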