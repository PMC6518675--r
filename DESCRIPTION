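Package: lncflux
Title: Long Noncoding RNA Discovery and Expression Analysis for
    High-Intake Feeding Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for bulk RNA-seq studies of scheduled
    high-intake (foie-gras style) feeding in waterfowl. Discovers putative
    long noncoding RNAs from assembled transcripts by a filter cascade
    (reference class-code removal, minimum spliced length, coding-potential
    score, exon count), classifies them into five positional categories
    relative to the nearest protein-coding gene, annotates cis-acting
    candidates within a 10 kb window, summarises differential expression
    with Welch tests and Benjamini-Hochberg correction, decomposes
    expression variance over tissue and treatment by a principal variance
    component analysis, predicts lncRNA function by thresholded Pearson
    co-expression with mRNAs, categorizes orthologous gene families by copy
    number, tests gene-set enrichment among differentially expressed genes
    by contingency chi-square, and models the force-feeding schedule's
    cumulative energy intake. A seeded synthetic-data generator with
    planted ground truth makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
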