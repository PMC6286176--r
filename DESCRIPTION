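Package: methseek
Title: Coverage-Threshold Methylation Peak Calling for MBD-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls DNA methylation peaks from MBD-Seq fragment alignments by
    scanning promoter and intragenic windows for maximal runs of bases whose
    read depth meets a threshold, consolidates per-sample peak lists into a
    merged master list of methylation sites, builds site-by-sample read count
    matrices, and screens for differential enrichment between two conditions
    with median-of-ratios normalization, log2 fold changes and a label
    permutation test. Includes an MBD-Seq fragment simulator with planted
    methylated promoter regions so the full pipeline can be validated against
    known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
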