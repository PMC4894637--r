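Package: mirdisco
Title: Discovery of Canonical and Non-Canonical miRNAs from Three-Strain Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying microRNAs from small RNA
    sequencing of a wild-type strain, a miRNA-processing mutant (microprocessor
    knockout, in which miRNAs are lost) and a suppressor mutant (Argonaute
    knockout, in which miRNAs accumulate). Collapsed reads are placed on the
    genome by exact matching on both strands, quantified in +/- 5 nt windows
    around candidate mature arms, and normalized to reads per million. Six
    identification criteria (mature length 20-24 nt, >= 3-fold up in the
    suppressor, >= 3-fold down in the processing mutant, hairpin context,
    detectable star arm, Northern blot evidence) classify each locus as a
    canonical miRNA, a non-canonical miRNA-like RNA, or rejected. Hairpin
    context is assessed with a maximum base-pairing (Nussinov) dynamic program
    and star arms are predicted with 2-nt 3' overhang duplex geometry. A
    synthetic-data generator plants hairpin loci with realistic strain fold
    structure and provides ground truth for recovery benchmarks.
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
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    jsonlite,
    optparse
Config/testthat/edition: 3
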