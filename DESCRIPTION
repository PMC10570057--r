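Package: TEchimR
Title: Detection of Gene-Transposable Element Chimeric Transcripts from
    Paired-End RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects chimeric transcripts formed between genes and
    transposable elements (TEs) from stranded paired-end RNA-seq.  A
    genome-guided mode classifies chimeras by the position of the TE
    insertion relative to the gene (TE-initiated, TE-exonized with
    embedded/overlapped/intronic subcategories, TE-terminated); a
    genome-blind mode detects chimeras, including those from TE insertions
    absent from any reference, by matching read mates across independent
    alignments to a transcript set and a TE set, optionally augmented by
    assembled-transcript evidence passed through an 80/80 homology filter.
    Includes the standard TE-annotation filters (minimum insertion length,
    simple-sequence-repeat content), a unique-fragment FPKM expression
    gate, replicate-consensus filtering of artifactual chimeric read
    pairs, and a seeded synthetic fixture generator with an ideal aligner
    so the whole pipeline is testable without external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicAlignments,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
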