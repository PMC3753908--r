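Package: derepress
Title: Positional Clustering, Repeat Enrichment and Methylation Analysis of
    Derepressed Gene Sets
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls derepressed genes from a wild-type versus mutant log2
    expression matrix using moderated t-statistics with empirical-Bayes
    variance shrinkage and Benjamini-Hochberg false-discovery-rate control,
    aggregates probe-set calls to genes, tests whether affected genes cluster
    along a chromosome with a median-distance resampling null, tests repeat
    family enrichment inside the clusters against size-matched random regions
    with a Wilcoxon rank-sum test, and compares CpG methylation between
    genotypes from percent-methylation tables and bisulfite clone sequences.
    Includes a synthetic-data generator that plants clusters of modestly
    upregulated genes (monoallelic-to-biallelic shifts, at most 2-fold),
    enriched repeat families and hypomethylated amplicons with a ground-truth
    table, so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
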