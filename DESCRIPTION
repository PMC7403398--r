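Package: lethscan
Title: Genome-Wide Scan for Recessive Lethal Haplotypes from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate recessive embryonic-lethal haplotypes in
    livestock SNP genotype data by scanning for Hardy-Weinberg deviations with
    an absence of minor-allele homozygotes. Implements the conditional exact
    Hardy-Weinberg test, Benjamini-Hochberg and Storey false discovery rate
    adjustment, adjacency clustering of flagged markers into candidate blocks,
    EM estimation of two-locus haplotype frequencies for r-squared and D-prime
    shortlisting of linked variants, Gaussian mixture re-calling of genotypes
    from raw array intensities, and a forward simulator of survivor genotypes
    under a homozygous-lethal haplotype for power analysis and validation.
    Reads PLINK text (PED/MAP) and VCF genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
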