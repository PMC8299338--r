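#!/usr/bin/env Rscript
# Stage 2: quality control.
#
# Re-reads the simulated VCFs and applies the variant filters (call rate
# 0.95, MAF 0.05, HWE exact p 0.001, duplicate positions) and PI_HAT
# relatedness pruning (threshold 0.1). The simulated samples are drawn
# without replacement from one pedigree-free population, so few removals
# are expected; the stage demonstrates the filters and records the counts.

library(dcmscan)

for (scenario in c("sweep", "neutral")) {
  dir <- file.path("results/data", scenario)
  sub <- utils::read.delim(file.path(dir, "subpops.tsv"))
  hm <- read_phased_vcf(file.path(dir, "simulated.vcf"), sub)

  fv <- filter_variants(hm, qc_config())
  rel <- exclude_related(fv$hapmat, pihat_max = 0.1)
  rep_df <- data.frame(filter = c("input", "call_rate", "maf", "hwe",
                                  "duplicate", "surviving_variants",
                                  "samples_removed_related"),
                       count = c(fv$report$n_input,
                                 fv$report$callrate_removed,
                                 fv$report$maf_removed,
                                 fv$report$hwe_removed,
                                 fv$report$duplicate_removed,
                                 fv$report$n_surviving,
                                 length(rel$removed_ids)))
  out <- file.path("results", paste0("qc_report_", scenario, ".tsv"))
  utils::write.table(rep_df, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message(scenario, ": ", fv$report$n_surviving, "/", fv$report$n_input,
          " variants survive QC; ", length(rel$removed_ids),
          " samples removed for relatedness (see ", out, ")")
}
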