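Package: canidcnv
Title: Copy Number Variant Discovery and Population Differentiation in
    Wolf-Like Canids from Array CGH Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of an array comparative genomic
    hybridization (aCGH) copy-number pipeline for wolf-like canids:
    two-stage CNV discovery (hidden Markov model segmentation combined
    with a robust run-length caller, posterior filtering, within-sample
    and cross-sample merging), three-state genotyping against chip-wide
    log2-ratio statistics, population genetics of CNV genotypes (EM
    allele frequencies under Hardy-Weinberg, expected heterozygosity,
    the VST differentiation statistic, wolf-subsampling comparisons),
    breakpoint architecture analyses (GC peaks, perfect-homology
    permutation tests, repeat enrichment), gene-overlap randomization
    tests, and a synthetic-data generator that emulates the array design
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
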