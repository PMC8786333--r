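Package: ironSplice
Title: Joint Differential Expression and Differential Alternative Splicing
    Calling from Feature-Level RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for calling differential gene expression (DE) and
    differential alternative splicing (DAS) from feature-level RNA-seq
    coverage of a short-term iron-deficiency time course, and for relating
    the mode of regulation to gene architecture. Implements quality-score
    running-sum read trimming, TMM/logCPM/adjusted-RPKM normalization with
    an expression-relevance filter, per-timepoint t-test DE calling,
    intron-retention / alternative donor-acceptor / exon-skipping ratio
    statistics with replicate-presence filtering, regulatory-mode
    classification (DE-only, DAS-only, both), splice-site-strength and
    intron-number association analyses, and k-of-n consensus voting across
    independent datasets ("ferrome"). A synthetic-data generator with known
    ground truth emulates the 3-vs-3 multi-timepoint design so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    edgeR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr,
    optparse
biocViews: RNASeq, AlternativeSplicing, DifferentialExpression,
    DifferentialSplicing, Normalization, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'architecture.R'
    'consensus.R'
    'coverage.R'
    'de.R'
    'gene-models.R'
    'ironSplice-package.R'
    'modes.R'
    'normalize.R'
    'pipeline.R'
    'splicing.R'
    'synthetic.R'
    'trim.R'
    'utils.R'
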