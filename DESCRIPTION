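Package: delinscan
Title: Haplotype-Resolved Detection of Complex Indels from Noisy Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects delins (complex indels), insertions and deletions from
    high-error (~15%) long-read alignments via a Gaussian-weighted variation
    density score, classifies candidate regions with one-vs-one support vector
    machines, resolves breakpoints from soft-clip clusters with Tukey outlier
    removal, traces the genomic origin of inserted fragments by iterative
    re-alignment of clipped sequence, and phases all variants into haplotype
    blocks using read-backed splicing followed by linkage-disequilibrium based
    secondary splicing. Ships a seeded diploid simulator producing CLR-like
    reads, truth files and truth-derived alignments so the whole pipeline is
    testable without an external aligner or dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    e1071,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
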