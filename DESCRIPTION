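Package: trcmap
Title: Mapping DNA Double-Strand Breaks and Transcription-Replication
    Conflicts from BLISS Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide analysis of DNA double-strand breaks
    (DSBs) mapped by sBLISS (in situ break labeling and sequencing):
    prefix parsing and demultiplexing of UMI-tagged break reads,
    mismatch-tolerant UMI deduplication, library down-sampling, fixed-bin
    hotspot calling with gap merging and replicate union, genomic
    annotation of break-enriched regions against promoters, gene bodies,
    early-replicated regions and S-phase transcripts, classification of
    transcription-replication conflicts as head-on or co-directional from
    replication-fork direction inferred around replication origins, and
    spike-in based size-factor normalization of EU-seq/DRIP-seq count
    tables. Includes a synthetic-data generator with ground truth so every
    stage of the pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
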