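Package: recmapr
Title: Autozygosity Mapping and Recessive Variant Filtering in Half-Sib Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping fully penetrant recessive defects in
    livestock half-sib families: SNP-array quality control, sliding-window
    haplotype association with Fisher's exact test of allelic association,
    runs-of-homozygosity detection and case/control autozygosity mapping,
    Mendelian recessive-compatibility filtering of regional multi-sample
    variant tables, single-exon skipping consequence prediction on gene
    models, and cohort incidence statistics. Includes a synthetic-data
    generator for half-sib cohorts segregating a planted recessive
    haplotype, with ground-truth records for recovery testing, plus
    readers and writers for PLINK PED/MAP, minimal VCF, GFF3, FASTA and
    BED.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
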