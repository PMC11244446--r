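Package: gevescan
Title: Methylome-Guided Discovery of Endogenized Viral Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects giant endogenous viral elements (GEVEs), adintovirus
    insertions and Plavaka-type giant repeats from whole-genome cytosine
    methylation data. Classifies CpG sites by their extended trinucleotide
    context (the symmetric CGC/GCG family versus other CG), computes weighted
    methylation statistics and spike-in conversion QC, builds
    expression-stratified metagene and transposable-element methylation
    profiles, segments the genome into hypermethylated islands from the
    non-CGC/GCG signal with sub-window boundary refinement, classifies islands
    with gene-architecture features and viral marker-gene evidence, and
    quantifies the promoter-methylation/silencing relationship under
    demethylating-agent treatment (promoter deciles versus differential
    expression, reactivation categories, Fisher exact domain enrichment).
    Ships a seeded synthetic-methylome generator with ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
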