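Package: SRPSseq
Title: Selective RNA Processing and Stabilization Analysis from Paired
    dRNA-Seq Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery pipeline for selective RNA processing and
    stabilization (SRPS) in bacterial operons from paired dRNA-Seq
    libraries. Starting from stranded read 5'-start tracks of an
    exonuclease-treated library (Exo, primary transcripts only) and a
    hybridization rRNA-subtracted library (Hyb, all transcripts), the
    package calls transcriptional start sites and processed sites by
    differential Exo/Hyb enrichment, assembles an operon map, classifies
    intra-operon transcript-abundance polarity patterns, tests
    hypergeometric enrichment of processed-site categories across
    patterns, and relates the folding free energy of stem-loops near
    intergenic processed sites to the abundance ratio of their flanking
    transcripts. A synthetic-data generator with planted ground truth
    provides a self-contained test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    jsonlite,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneRegulation, Sequencing, Software
RoxygenNote: 7.3.3
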