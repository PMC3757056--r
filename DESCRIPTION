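Package: epiTempo
Title: Timing of Transcriptional and H3K27me3 Chromatin Changes in
    Signaling Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare the timing of signal-induced changes in
    transcription with changes in H3K27me3 chromatin modification over a
    sampled time course. Provides length-normalized metagene profiling of
    binned ChIP-seq coverage (600 points per gene across upstream, gene
    body and downstream segments), region-mean signal quantification over
    gene bodies and TSS windows, fold-change based differential calling,
    hierarchical clustering of spatial and temporal profiles, the
    interpolated half-transition time ("t-half") statistic with cohort
    lead/lag summaries, detection of intergenic candidate transcripts from
    strand-split coverage, small qPCR quantification helpers, and a
    synthetic-data generator with known lead/lag ground truth that
    exercises every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
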