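Package: ptcrescue
Title: Transcript-Aware Classification of Premature Termination Codon
    Mutations from Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to classify premature termination codon (PTC) mutations
    from coding-HGVS nomenclature, to quantify PTC-bearing, wild-type and
    frame-rescued transcripts from noisy spliced long-read amplicon cDNA
    alignments (nonsense-mediated decay escape, in-frame exon skipping,
    cryptic splice-site usage, intron retention), and to run stratified
    case-control association statistics (Cochran-Mantel-Haenszel odds
    ratios, exact Hardy-Weinberg tests, pairwise linkage disequilibrium,
    spectral-decomposition multiple-testing thresholds). Includes a
    synthetic-data generator that emulates amplicon cDNA reads drawn from
    a two-allele transcript pool with tunable NMD degradation, rescue
    isoform proportions and a nanopore-like error profile.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
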