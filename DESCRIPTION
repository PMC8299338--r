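Package: dcmscan
Title: De-Correlated Composite Selection Signature Scans for SNP Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scan for signatures of selection in livestock SNP array
    data. Computes five per-SNP univariate statistics (Weir-Cockerham FST
    between two subpopulations, Garud H1 and H12 haplotype homozygosity,
    binned Tajima's D, per-site nucleotide diversity), combines them into
    the De-correlated Composite of Multiple Selection Signals (DCMS) via
    fractional-rank p-values weighted by a robust (MCD) correlation matrix,
    fits a robust normal to the composite, and calls significant genomic
    regions from Benjamini-Hochberg q-values. Includes quality-control
    filters (call rate, MAF, Hardy-Weinberg exact test, duplicate positions,
    PI_HAT relatedness pruning), gene/QTL interval annotation with a
    chromosome-based bootstrap QTL-enrichment test, and a forward
    Wright-Fisher simulator of hard selective sweeps for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
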