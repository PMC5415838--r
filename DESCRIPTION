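Package: mirsat
Title: Small RNA-Seq miRNA Profiling for Muscle Satellite Cell Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained small RNA sequencing analysis pipeline for
    profiling microRNA expression across differentiation stages of muscle
    derived satellite cells. Implements raw-read cleaning (quality filter,
    3' adapter trimming, contaminant classification), collapsing of reads to
    unique tags, genome mapping and an annotation priority cascade over
    non-coding RNA and gene features, identification of conserved miRNAs by
    perfect mature-plus-precursor matching, discovery of novel miRNA
    candidates by hairpin screening with explicit minimum free energy, MFEI,
    AU-content and duplex-mismatch criteria, count normalization to reads per
    million with the exact two-library count statistic of Audic and Claverie
    for differential expression, seed-complementarity target prediction with
    Allen-style penalty scoring, and relative RT-qPCR quantification. A
    seeded synthetic-data generator produces genomes, annotations, miRNA
    references and FASTQ libraries with a planted ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
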