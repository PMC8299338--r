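#!/usr/bin/env Rscript
# Stage 1: generate the study datasets.
#
# Two phased SNP datasets at the default study conditions (200 breeding
# diploids, 3 chromosomes x 2,000 SNPs at 25 kb spacing, 200 burn-in
# generations): one carrying a hard selective sweep (s = 0.05 planted at 5%
# standing frequency, 150 generations of selection) and one fully neutral.
# Each is then split into founder / farm-born subpopulations (25% founders,
# 10 generations of drift) to support the two-subpopulation FST.

library(dcmscan)

seed <- 20260920L
outdir <- "results/data"

for (scenario in c("sweep", "neutral")) {
  s <- if (scenario == "sweep") 0.05 else 0
  off <- if (scenario == "sweep") 0L else 1L
  sim <- simulate_population(
    sweep_sim_config(s = s, seed = derive_seed(seed, "simulate") + off))
  hm <- split_subpopulations(sim$hapmat,
                             seed = derive_seed(seed, "split") + off)
  paths <- write_simulation(hm, sim$truth, file.path(outdir, scenario))
  message(sprintf(
    "%s: %d samples x %d SNPs written; sweep=%s final freq=%.3f",
    scenario, n_samples(hm), n_loci(hm), sim$truth$sweep,
    sim$truth$f_final))
}
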