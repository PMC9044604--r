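Package: sexscan
Title: Detection of Sex-Linked Genomic Regions from Whole-Genome
    Sequencing Coverage and Heterozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies sex chromosomes and other sex-linked genomic
    regions from whole-genome sequencing alignments of male and female
    samples mapped to a homogametic reference genome. Computes
    mismatch-stratified genome coverage and per-sample heterozygosity in
    genome windows, normalizes coverage between samples after masking
    extreme-depth windows, contrasts the heterogametic against the
    homogametic sex, and flags windows outside an empirical 95% band as
    candidate sex-linked regions. Optionally lifts window coordinates
    onto a second species' assembly through whole-genome-alignment
    blocks. Ships a synthetic-data generator producing reference FASTA,
    aligned BAM, multi-sample VCF and synteny-map fixtures for the
    canonical differentiation scenarios, five diagnostic plot types, and
    a static HTML report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
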