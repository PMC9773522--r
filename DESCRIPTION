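Package: placentaSexDE
Title: Sex-Chromosome-Complement-Aware Differential Expression for Placental RNA-seq
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing sex differences in bulk RNA-seq gene
    expression with explicit handling of the sex chromosomes. Provides sample
    sex-chromosome-complement inference from Y-linked marker and XIST
    expression, complement-specific hard masking of reference FASTA files,
    sample quality-control filters, trimmed-mean-of-M-values (TMM)
    normalization, prior-augmented log2-CPM transformation, voom-style
    precision weights, per-gene weighted linear models with empirical-Bayes
    variance moderation and Benjamini-Hochberg adjustment, X-Y gametolog
    expression analysis under X-only and X-plus-Y-summed accounting, and
    gene-class-stratified correlation of log2 female-to-male expression
    ratios across tissues. A negative-binomial simulator with known ground
    truth emulates the structure of a placental sex-differences study so the
    whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'synthetic-data.R'
    'preprocess-qc.R'
    'expression-core.R'
    'de-model.R'
    'gametolog.R'
    'crosstissue.R'
    'pipeline.R'
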