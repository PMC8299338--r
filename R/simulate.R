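#' Sweep-simulation configuration
#'
#' Defaults emulate the structure of a medium-density SNP-array dataset from
#' a closed cattle herd: ~150 sampled diploids, a few thousand mapped SNPs
#' per chromosome with array-like U-shaped founder allele frequencies, LD
#' built up by finite-population reproduction, and a single hard sweep from
#' standing variation.
#'
#' @param n_diploids breeding population size (default 200).
#' @param n_snps SNPs per chromosome (default 2000).
#' @param n_chroms number of chromosomes (default 3).
#' @param snp_spacing_bp distance between adjacent SNPs (default 25 kb).
#' @param recomb_rate per-interval per-meiosis crossover probability
#'   (default 1e-3).
#' @param s selection coefficient of the beneficial allele (additive
#'   viability 1, 1+s, 1+2s); 0 gives a neutral simulation. Default 0.05.
#' @param f0 frequency at which the beneficial allele is planted
#'   (default 0.05).
#' @param sweep_chrom,sweep_index chromosome (1-based) and SNP index within
#'   it of the focal site; defaults: chromosome 1, middle SNP.
#' @param burnin_gens neutral generations building drift and LD
#'   (default 200).
#' @param selection_gens generations of selection after planting
#'   (default 150).
#' @param sample_n diploids sampled at the end (default 150).
#' @param seed integer seed.
#' @return a `sweep_sim_config` list.
#' @export
sweep_sim_config <- function(n_diploids = 200L, n_snps = 2000L, n_chroms = 3L,
                             snp_spacing_bp = 25000L, recomb_rate = 1e-3,
                             s = 0.05, f0 = 0.05, sweep_chrom = 1L,
                             sweep_index = NULL, burnin_gens = 200L,
                             selection_gens = 150L, sample_n = 150L,
                             seed = 1L) {
  if (is.null(sweep_index)) sweep_index <- as.integer(ceiling(n_snps / 2))
  if (f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  if (s < 0) stop("s must be >= 0")
  if (sweep_index < 1 || sweep_index > n_snps) stop("sweep_index out of bounds")
  if (sweep_chrom < 1 || sweep_chrom > n_chroms) stop("sweep_chrom out of bounds")
  if (sample_n > n_diploids) stop("cannot sample more diploids than exist")
  structure(list(n_diploids = as.integer(n_diploids),
                 n_snps = as.integer(n_snps), n_chroms = as.integer(n_chroms),
                 snp_spacing_bp = as.integer(snp_spacing_bp),
                 recomb_rate = recomb_rate, s = s, f0 = f0,
                 sweep_chrom = as.integer(sweep_chrom),
                 sweep_index = as.integer(sweep_index),
                 burnin_gens = as.integer(burnin_gens),
                 selection_gens = as.integer(selection_gens),
                 sample_n = as.integer(sample_n), seed = as.integer(seed)),
            class = "sweep_sim_config")
}

sim_map <- function(cfg) {
  data.frame(
    chrom = as.character(rep(seq_len(cfg$n_chroms), each = cfg$n_snps)),
    pos = rep(seq_len(cfg$n_snps) * cfg$snp_spacing_bp, cfg$n_chroms),
    id = paste0("snp", seq_len(cfg$n_chroms * cfg$n_snps)),
    ref = "A", alt = "C", stringsAsFactors = FALSE)
}

# one WF generation: pick parent pairs (optionally fitness-weighted on the
# focal column) and produce recombinant offspring haplotypes
wf_generation <- function(H, chrom_id, recomb_rate, n_offspring,
                          focal_col = NULL, s = 0) {
  N <- nrow(H) / 2L
  if (!is.null(focal_col) && s > 0) {
    dosage <- H[seq(1L, 2L * N, by = 2L), focal_col] +
      H[seq(2L, 2L * N, by = 2L), focal_col]
    w <- 1 + s * dosage
  } else {
    w <- rep(1, N)
  }
  parents <- matrix(sample.int(N, 2L * n_offspring, replace = TRUE,
                               prob = w) - 1L, ncol = 2)
  wf_offspring(H, chrom_id, parents, recomb_rate)
}

#' Forward Wright-Fisher simulation of a hard selective sweep
#'
#' Four phases: (i) founder haplotypes drawn site-wise from Beta(0.5, 0.5)
#' allele frequencies truncated to `[0.05, 0.95]` (the U-shape of array
#' ascertainment, kept clear of the MAF filter); (ii) `burnin_gens` neutral
#' Wright-Fisher generations building drift and LD; (iii) the beneficial
#' allele planted at frequency `f0` at the focal site, then `selection_gens`
#' generations with additive viability 1, 1+s, 1+2s; (iv) `sample_n`
#' diploids sampled without replacement. If the beneficial allele is lost
#' before sampling the simulation restarts with an incremented seed (up to
#' 10 times, then errors).
#'
#' @param cfg a [sweep_sim_config()].
#' @return list: `hapmat`, `truth` (data frame with focal chromosome,
#'   position, column index, planted and final allele frequency, `s`, the
#'   seed actually used and whether a sweep was simulated).
#' @export
simulate_population <- function(cfg = sweep_sim_config()) {
  for (try in 0:10) {
    seed <- cfg$seed + try
    out <- withr::with_seed(seed, simulate_population_once(cfg))
    if (!is.null(out)) {
      out$truth$seed_used <- seed
      return(out)
    }
    if (try == 10) stop("beneficial allele lost in 10 consecutive restarts")
  }
}

simulate_population_once <- function(cfg) {
  map <- sim_map(cfg)
  chrom_id <- as.integer(map$chrom)
  L <- nrow(map)
  nh <- 2L * cfg$n_diploids

  freq <- stats::rbeta(L, 0.5, 0.5)
  freq <- pmin(pmax(freq, 0.05), 0.95)
  H <- matrix(stats::rbinom(nh * L, 1L, rep(freq, each = nh)), nrow = nh)
  storage.mode(H) <- "integer"

  if (cfg$burnin_gens > 0)
    H <- wf_evolve(H, chrom_id, cfg$burnin_gens, cfg$recomb_rate, -1L, 0)$H

  focal <- (cfg$sweep_chrom - 1L) * cfg$n_snps + cfg$sweep_index
  sweep <- cfg$s > 0
  if (sweep) {
    # plant the beneficial allele on a random set of haplotypes at f0
    carriers <- sample.int(nh, max(1L, round(cfg$f0 * nh)))
    H[, focal] <- 0L
    H[carriers, focal] <- 1L
    ev <- wf_evolve(H, chrom_id, cfg$selection_gens, cfg$recomb_rate,
                    focal - 1L, cfg$s)
    if (ev$lost) return(NULL)  # lost: caller restarts
    H <- ev$H
  }

  keep <- sort(sample.int(cfg$n_diploids, cfg$sample_n))
  hap_rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  hm <- hap_matrix(H[hap_rows, , drop = FALSE], map,
                   sprintf("ind%03d", seq_len(cfg$sample_n)))
  truth <- data.frame(
    sweep = sweep,
    sweep_chrom = if (sweep) as.character(cfg$sweep_chrom) else NA_character_,
    sweep_pos = if (sweep) map$pos[focal] else NA_integer_,
    sweep_col = if (sweep) focal else NA_integer_,
    f0 = cfg$f0, s = cfg$s,
    f_final = mean(hm$alleles[, focal]),
    stringsAsFactors = FALSE)
  list(hapmat = hm, truth = truth)
}

#' Split samples into founder and farm-born subpopulations
#'
#' Emulates the two herd strata used for FST: a `founder_fraction` of the
#' samples keeps its genotypes and is labelled `"founder"`; the remaining
#' samples are replaced by descendants produced by `drift_gens` further
#' neutral Wright-Fisher generations seeded from the full sample, and
#' labelled `"farmborn"`. More drift generations mean more differentiation.
#'
#' @param x a `hapmat`.
#' @param founder_fraction fraction of samples frozen as founders
#'   (default 0.25).
#' @param drift_gens neutral generations separating the strata (default 10).
#' @param seed integer seed.
#' @return the `hapmat` with `subpop` labels attached.
#' @export
split_subpopulations <- function(x, founder_fraction = 0.25, drift_gens = 10L,
                                 seed = 1L) {
  if (drift_gens < 0) stop("drift_gens must be >= 0")
  n <- n_samples(x)
  n_f <- round(founder_fraction * n)
  chrom_id <- as.integer(factor(x$map$chrom, levels = unique(x$map$chrom)))
  withr::with_seed(seed, {
    founders <- sort(sample.int(n, n_f))
    H <- x$alleles
    for (g in seq_len(drift_gens))
      H <- wf_generation(H, chrom_id, attr(x, "recomb_rate") %||% 1e-3, n)
    desc <- setdiff(seq_len(n), founders)
    A <- x$alleles
    hap_rows <- as.vector(rbind(2L * desc - 1L, 2L * desc))
    A[hap_rows, ] <- H[hap_rows, , drop = FALSE]
    subpop <- rep("farmborn", n)
    subpop[founders] <- "founder"
    hap_matrix(A, x$map, x$sample_ids, subpop)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated dataset to disk
#'
#' Emits a phased VCF, a subpopulation table and a truth TSV; the VCF
#' round-trips through [read_phased_vcf()] with exact allele equality.
#'
#' @param x a `hapmat` (with subpop labels, if assigned).
#' @param truth truth data frame from [simulate_population()].
#' @param outdir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_simulation <- function(x, truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(outdir, "simulated.vcf")
  write_phased_vcf(x, vcf)
  sub <- file.path(outdir, "subpops.tsv")
  utils::write.table(
    data.frame(sample = x$sample_ids,
               subpop = x$subpop %||% rep("all", n_samples(x))),
    sub, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- file.path(outdir, "truth.tsv")
  utils::write.table(truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  c(vcf = vcf, subpops = sub, truth = tr)
}
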