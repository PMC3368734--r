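Package: placentome
Title: Multi-Tissue RNA-Seq Enrichment, Splicing and Novel-Transcript Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing a panel of target tissues (for example the
    three placental compartments: amnion, chorion and decidua) against a
    background tissue panel from bulk RNA-Seq summaries. Implements exon-union
    FPKM quantification with tissue-enriched and tissue-specific gene calling,
    junction-count based exon inclusion (PSI) estimation with a Bayesian
    differential-splicing test, Fisher's exact gene-set overlap enrichment,
    and clustering of reconstructed transcripts into transcriptional active
    regions (TARs) with novelty classification of TARs and their internal
    exons. A seeded synthetic-cohort generator with planted ground truth makes
    every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: RNASeq, AlternativeSplicing, GeneExpression, Transcriptomics
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'expression.R'
    'io.R'
    'overlap.R'
    'splice.R'
    'synthetic.R'
    'pipeline.R'
    'tar.R'
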