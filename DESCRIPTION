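Package: svldscan
Title: Linkage-Disequilibrium Scans Between Structural Variants and
    GWAS-Significant SNPs from Unphased Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the genotypic squared correlation (g-squared) between
    biallelic structural variants (SVs) and nearby genome-wide-significant
    GWAS SNPs directly from unphased diploid genotypes, without a phasing
    step. Reads SV and SNP genotype panels from VCF, parses GWAS-catalog
    style association tables, enumerates candidate SV-SNP pairs within a
    physical window flanking each SV's endpoints, and emits a filtered
    SV-SNP-trait catalog of pairs in high linkage disequilibrium. Includes
    a synthetic-data generator that plants two-locus haplotype structure at
    controlled r-squared so every pipeline stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
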