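Package: line1scan
Title: Detection, Annotation and Association Testing of LINE-1 Insertions
    from Short-Read Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for discovering intronic
    LINE-1 retrotransposon insertions from paired-end short-read alignments
    and testing them for association with a recessive phenotype. Provides a
    structural-variant read simulator (reference window, full-length LINE-1
    element with target site duplication, diploid cohorts with incomplete
    penetrance), a soft-clip cluster breakpoint detector with target-site-
    duplication inference, a greedy overlap assembler and LINE-1 structural
    annotator (ORF1, spacer, ORF2, poly-A, orientation), read-support
    genotyping with in-silico amplicon sizing, and an exact and model-based
    association battery (Freeman-Halton r x c exact test, per-allele and
    genotypic logistic regression with likelihood-ratio model-shape test,
    genotype-dosage LD r-squared, concordance summaries) implemented from
    first principles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
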