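Package: cronoscan
Title: Position-Dependent Consequences of Titin Truncations from Splicing,
    Decay and Internal-Promoter Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to explain why truncating variants in the giant sarcomeric
    gene Titin (TTN/ttna) have position-dependent severity. Implements
    exon-level percent-spliced-in (PSI) estimation from exon-exon junction
    reads with a read-sufficiency no-call filter, splice-aware
    truncation-consequence calling (nonsense/frameshift, phase-based
    exon-skip and in-silico intron-retention rules), nonsense-mediated decay
    estimation from allelic imbalance in heterozygote amplicon sequencing,
    internal alternative-promoter detection from intronic read accumulation
    with epigenomic peak annotation and in-frame internal initiator search,
    positional cohort analysis relative to the internal (Cronos) promoter
    with a difference-in-proportions test, and CRISPR/Cas9 guide design by
    NGG PAM scanning with genome-uniqueness filtering. A synthetic-data
    module generates every consumed data type so the whole pipeline runs
    end-to-end without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
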