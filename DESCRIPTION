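Package: mitopause
Title: Mitochondrial RNA Polymerase Pause Calling and G-Quadruplex
    Association from Nascent-Transcription 3' Ends
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls RNA polymerase pause sites on a circular genome from
    strand-specific 3'-end coverage of nascent-transcription (PRO-seq)
    reads using a sliding-window Z-score statistic, scores G-quadruplex
    propensity of the underlying sequence (run-based per-base scores with
    windowed means, and four-tract motif enumeration with bounded loops),
    and computes the association statistics linking G4-forming sequence
    to pausing: anchor-centered metaprofiles, upstream-guanine enrichment,
    strand asymmetry, grouping by upstream guanine content, gene
    annotation and variant overlap. Includes a negative-binomial
    synthetic-data generator with planted motifs and pauses so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
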