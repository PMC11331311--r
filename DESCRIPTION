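Package: dcmscan
Title: Decorrelated Composite Selection Scans for Two-Population Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic signatures of selection in two-population phased
    genotype data. Implements runs-of-homozygosity calling with a sliding-window
    algorithm and the derived per-SNP autozygosity track, extended haplotype
    homozygosity (EHH) with integrated haplotype scores (iHS) and the
    cross-population XP-EHH statistic, a per-SNP fixation index against the
    mean-frequency baseline, and their combination into a decorrelated
    composite of multiple signals (DCMS) with empirical-normal p-values,
    Benjamini-Hochberg FDR control and merging of significant SNPs into
    genomic regions annotated with overlapping genes. Ships a two-population
    synthetic-data generator (Balding-Nichols differentiation, founder-mosaic
    linkage disequilibrium, hard-sweep injection, planted homozygous segments)
    with truth tables so the whole pipeline is testable without restricted
    livestock data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
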