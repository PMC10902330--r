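Package: rhythmscan
Title: Rhythm Detection and Phase-Binned Cis-Element Enrichment for
    Gene Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects periodic gene expression over configurable period
    windows (circadian ~20-28 h, developmental/molting ~8-10 h) by
    least-squares cosinor fitting with a block-permutation null and
    Benjamini-Hochberg correction; clusters rhythmic genes by cosine
    distance after amplitude normalization and assigns peak-phase bins;
    extracts regulatory regions (upstream plus introns) from FASTA/GFF3
    and scans degenerate IUPAC motifs such as the ROR response element
    on both strands; tests phase-binned cis-element enrichment with
    Fisher's exact test and Holm correction; quantifies overlap between
    rhythm sets detected at two periods and compares conditions against
    a time-shuffled null. Includes a synthetic-data module that plants
    known rhythms and motif instances so the whole pipeline is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
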