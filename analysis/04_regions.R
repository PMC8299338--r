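#!/usr/bin/env Rscript
# Stage 4: significant-region calling.
#
# Regions are maximal runs of SNPs with q <= 0.1 containing at least two
# consecutive SNPs with q < 0.05, summarised in the style of a genome-scan
# summary table (count, mean +/- SD length in kb, min/max, SNP count, total
# Mb) and exported as BED.

library(dcmscan)

for (scenario in c("sweep", "neutral")) {
  scan <- utils::read.delim(file.path("results",
                                      paste0("scan_", scenario, ".tsv")))
  scan$chrom <- as.character(scan$chrom)
  regions <- call_regions(scan, region_config())
  write_regions_bed(regions,
                    file.path("results", paste0("regions_", scenario, ".bed")))
  summ <- summarize_regions(regions)
  utils::write.table(summ,
                     file.path("results",
                               paste0("region_summary_", scenario, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: %d region(s); mean length %.1f kb; %d member SNPs; total %.2f Mb",
    scenario, summ$n_regions, summ$mean_kb, summ$n_snps, summ$total_mb))
}
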