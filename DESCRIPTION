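Package: flsplice
Title: Alternative-Splicing Analysis of Full-Length Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for alternative-splicing analysis of full-length
    (long-read) transcriptome data: classification of reads of insert into
    full-length and non-full-length categories by primer and poly(A)-tail
    detection, chimera flagging, collapse of transcript-to-genome alignments
    into unique isoforms, classification of alternative-splicing events
    (intron retention, exon skipping, alternative donor/acceptor, mutually
    exclusive exons), poly(A) cleavage-site calling and flanking-sequence
    profiling, consensus filtering of splice-junction call sets from
    multiple callers, Jensen-Shannon tissue-specificity scoring, and
    stage-resolved expression analysis. Includes a synthetic-transcriptome
    simulator with ground-truth manifests so every stage of the pipeline can
    be validated against planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
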