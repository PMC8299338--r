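#' Quality-control configuration
#'
#' Thresholds mirror the standard SNP-array QC applied to the genotype data:
#' variants are dropped below a 0.95 genotype call rate, below 0.05 minor
#' allele frequency or with a Hardy-Weinberg exact-test p below 0.001;
#' samples are pruned until no pair shares PI_HAT above 0.1.
#'
#' @param min_call_rate minimum per-variant genotype call rate.
#' @param min_maf minimum minor-allele frequency.
#' @param hwe_p_floor variants with HWE exact p below this are removed.
#' @param pihat_max maximum tolerated pairwise PI_HAT.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_call_rate = 0.95, min_maf = 0.05,
                      hwe_p_floor = 0.001, pihat_max = 0.1) {
  cfg <- list(min_call_rate = min_call_rate, min_maf = min_maf,
              hwe_p_floor = hwe_p_floor, pihat_max = pihat_max)
  if (any(unlist(cfg) < 0 | unlist(cfg) > 1))
    stop("all QC thresholds must lie in [0, 1]")
  structure(cfg, class = "qc_config")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote configurations whose conditional
#' probability does not exceed that of the observed configuration (two-sided
#' by probability mass).
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return the exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(c(n_AA, n_Aa, n_aa) %% 1 != 0))
    stop("genotype counts must be non-negative integers")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  # heterozygote count shares the parity of min(nA, na)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  # log conditional probability of each possible het count given allele counts
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Variant-level QC filters
#'
#' Applies, in order, the call-rate, MAF, HWE and duplicate-position filters
#' (each to the survivors of the previous one) and reports per-filter removal
#' counts. The fixed order makes the per-filter counts reproducible.
#'
#' @param x a `hapmat`.
#' @param qc a [qc_config()].
#' @return list with the filtered `hapmat` and a `report` (per-filter counts
#'   and surviving dimensions); removed + surviving = input per axis.
#' @export
filter_variants <- function(x, qc = qc_config()) {
  g <- genotype_dosage(x)
  ns <- n_samples(x)
  keep <- rep(TRUE, n_loci(x))
  report <- list(n_input = n_loci(x))

  call_rate <- colMeans(!is.na(g))
  fail <- keep & call_rate < qc$min_call_rate
  report$callrate_removed <- sum(fail)
  keep <- keep & !fail

  n_called <- 2 * colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  freq <- ifelse(n_called > 0, alt / n_called, 0)
  maf <- pmin(freq, 1 - freq)
  fail <- keep & maf < qc$min_maf
  report$maf_removed <- sum(fail)
  keep <- keep & !fail

  hwe_p <- rep(1, n_loci(x))
  for (j in which(keep)) {
    gj <- g[, j]
    hwe_p[j] <- hwe_exact_p(sum(gj == 0, na.rm = TRUE),
                            sum(gj == 1, na.rm = TRUE),
                            sum(gj == 2, na.rm = TRUE))
  }
  fail <- keep & hwe_p < qc$hwe_p_floor
  report$hwe_removed <- sum(fail)
  keep <- keep & !fail

  key <- paste(x$map$chrom, x$map$pos)
  # a duplicate only counts against survivors: the first *surviving* record
  # at a (chrom, pos) is kept
  first_seen <- !duplicated(ifelse(keep, key, NA_character_), incomparables = NA)
  fail <- keep & !first_seen
  report$duplicate_removed <- sum(fail)
  keep <- keep & !fail

  report$n_surviving <- sum(keep)
  out <- subset_hapmat(x, loci = keep)
  list(hapmat = out, report = report)
}

#' Pairwise PI_HAT relatedness
#'
#' Method-of-moments identity-by-descent estimation: from the observed
#' identity-by-state counts of each sample pair and the sample allele
#' frequencies, the expected IBS counts under IBD states 0/1/2 give estimates
#' of P(IBD=0), P(IBD=1), P(IBD=2); negative components are truncated to 0
#' and the triple renormalised. PI_HAT = P(IBD=2) + P(IBD=1)/2.
#'
#' @param x a `hapmat` with at least 2 samples.
#' @return symmetric matrix of PI_HAT values with `NA` diagonal.
#' @export
pihat_matrix <- function(x) {
  g <- genotype_dosage(x)
  ns <- nrow(g)
  if (ns < 2) stop("need at least 2 samples")
  n_called <- 2 * colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / pmax(n_called, 1)  # alt-allele frequency
  poly <- n_called > 0 & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci: IBD moments undefined")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]; q <- 1 - p

  # per-locus expected IBS-state probabilities under each IBD state
  e00 <- 2 * p^2 * q^2
  e10 <- 4 * p^3 * q + 4 * p * q^3
  e20 <- p^4 + q^4 + 4 * p^2 * q^2
  e11 <- 2 * p^2 * q + 2 * p * q^2
  e21 <- p^3 + q^3 + p^2 * q + p * q^2

  out <- matrix(NA_real_, ns, ns, dimnames = list(x$sample_ids, x$sample_ids))
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      d <- abs(g[i, ok] - g[j, ok])
      ibs0 <- sum(d == 2); ibs1 <- sum(d == 1); ibs2 <- sum(d == 0)
      E00 <- sum(e00[ok]); E10 <- sum(e10[ok]); E20 <- sum(e20[ok])
      E11 <- sum(e11[ok]); E21 <- sum(e21[ok]); N <- sum(ok)
      p0 <- if (E00 > 0) ibs0 / E00 else 0
      p1 <- if (E11 > 0) (ibs1 - p0 * E10) / E11 else 0
      p2 <- (ibs2 - p0 * E20 - p1 * E21) / N
      v <- pmax(c(p0, p1, p2), 0)
      if (sum(v) == 0) v <- c(1, 0, 0)
      v <- v / sum(v)
      out[i, j] <- out[j, i] <- min(1, v[3] + v[2] / 2)
    }
  }
  out
}

#' Greedy relatedness pruning
#'
#' Repeatedly removes the sample participating in the most pairs with
#' PI_HAT above `pihat_max` (ties broken by sample id) until no such pair
#' remains.
#'
#' @param x a `hapmat`.
#' @param pihat_max threshold above which a pair is considered related.
#' @param pihat optional precomputed [pihat_matrix()].
#' @return list with the pruned `hapmat` and `removed_ids`.
#' @export
exclude_related <- function(x, pihat_max = 0.1, pihat = NULL) {
  if (is.null(pihat)) pihat <- pihat_matrix(x)
  ids <- x$sample_ids
  active <- setNames(rep(TRUE, length(ids)), ids)
  adj <- pihat > pihat_max
  adj[is.na(adj)] <- FALSE
  removed <- character(0)
  repeat {
    deg <- rowSums(adj[active, active, drop = FALSE])
    if (!any(deg > 0)) break
    worst <- names(deg)[deg == max(deg)]
    victim <- sort(worst)[1]
    removed <- c(removed, victim)
    active[victim] <- FALSE
  }
  list(hapmat = subset_hapmat(x, samples = active), removed_ids = removed)
}
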