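Package: tumorvar
Title: Somatic SNV and InDel Calling for Tumor-Only and Tumor-Normal
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects somatic single-nucleotide variants, multi-nucleotide
    substitutions, insertions, deletions and complex (indel plus SNV)
    variants from aligned tumor sequencing reads, with or without a matched
    normal sample.  Candidate sites are scored with a Bayesian classifier
    log-odds (LOD) model; tumor-normal pairs are additionally screened with
    a cascade of normal-frequency gates and a one-sided Fisher's exact
    test.  Adjacent events observed on the same reads are merged into
    substitution and complex records, allele fractions are computed on
    PCR-duplicate-collapsed read groups, and calls pass a configurable
    filter ledger before VCF output.  Includes a seeded simulator that
    writes aligned reads with exact CIGARs for arbitrary variant
    haplotypes, and an evaluation harness computing precision, sensitivity
    and F1 against a truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    Rsamtools,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
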