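Package: starrkit
Title: Quantification and Classification of STARR-seq Enhancer Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies enhancer activity from self-transcribing active
    regulatory region sequencing (STARR-seq) read counts. Implements
    per-peak binomial significance of reporter transcription over
    transfected input, empirical-Bayes shrinkage of enrichment via a
    maximum-likelihood beta-binomial prior, empirical false discovery
    estimation from GC- and length-matched random genomic background,
    replicate-consistent peak calling, input-coupled normalization
    factors for negative-binomial differential activity testing between
    culture conditions, and chromatin-context classification of loci
    into active (C1), chromatin-masked (C2) and dormant (C3) classes.
    A synthetic-data generator with planted ground truth exercises the
    full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
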