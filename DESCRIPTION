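Package: meiscreen
Title: Mobile Element Insertion Characterization and Junction-Probe Cohort Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing structural variants in a disease gene
    from long-read sequencing evidence and screening short-read cohorts for
    them. Decomposes insertion calls into target-site duplication, poly-A/T
    tail and mobile-element body with consensus-library classification;
    clusters per-read insertion/deletion signatures into
    nucleotide-resolution calls with repeat-context annotation of
    breakpoints; designs allele-diagnostic junction k-mer probes and
    grep-equivalent search patterns; counts probe-matching reads to call
    genotypes across cohorts; quantifies soft-clipped read evidence; and
    performs pedigree-based phase inference and STR founder-haplotype
    analysis. Includes seeded simulators for reads, cohorts and STR family
    genotypes built around a reconstructed EYS AluYa5 insertion and exon
    32-33 deletion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
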