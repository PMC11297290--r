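Package: isochar
Title: Isoform Characterization and Splicing-Event Annotation for
    Long-Read Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes transcript models derived from long-read
    (PacBio Iso-Seq / Oxford Nanopore) sequencing against a reference
    annotation.  Flattens each gene into a single numbered exon model,
    calls alternative-splicing events per isoform (exon skipping, intron
    retention, alternative 5'/3' splice sites, alternative first/last
    exons, cryptic and novel exons), assigns SQANTI-style structural
    categories (FSM/ISM/NIC/NNC), filters and normalizes full-length
    read counts, computes isoform fractions and differential transcript
    usage metrics (total change, podium change, permutation tests),
    predicts open reading frames and nonsense-mediated-decay candidates,
    collapses transcripts to unique protein isoforms, and generates
    fully synthetic benchmark datasets with ground-truth event labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
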