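#' Windowing and smoothing configuration
#'
#' @param h_window SNPs per haplotype-homozygosity window (default 14).
#' @param h_step step between windows in SNPs (default 1).
#' @param tajima_bin_bp width of the non-overlapping Tajima's D bins in bp
#'   (default 300 kb).
#' @param smooth_k width of the running-median smoother in SNPs (odd,
#'   default 31).
#' @return a `window_config` list.
#' @export
window_config <- function(h_window = 14L, h_step = 1L,
                         tajima_bin_bp = 300000L, smooth_k = 31L) {
  if (h_window < 2) stop("h_window must be >= 2")
  if (smooth_k < 3 || smooth_k %% 2 == 0) stop("smooth_k must be odd and >= 3")
  structure(list(h_window = as.integer(h_window), h_step = as.integer(h_step),
                 tajima_bin_bp = as.integer(tajima_bin_bp),
                 smooth_k = as.integer(smooth_k)),
            class = "window_config")
}

#' Per-SNP Weir-Cockerham FST between two subpopulations
#'
#' The 1984 variance-component estimator theta for two populations of
#' diploids, computed from genotype counts with the heterozygosity
#' correction. Negative estimates are clamped to 0; SNPs monomorphic across
#' both subpopulations are returned as `NA`.
#'
#' @param x a `hapmat` whose `subpop` labels define exactly two groups.
#' @return numeric vector of per-SNP FST in `[0, 1]` (or `NA`).
#' @export
weir_cockerham_fst <- function(x) {
  if (is.null(x$subpop)) stop("hapmat carries no subpopulation labels")
  groups <- sort(unique(x$subpop))
  if (length(groups) != 2) stop("exactly two subpopulations required, got ",
                                length(groups))
  g <- genotype_dosage(x)
  res <- rep(NA_real_, ncol(g))
  idx <- lapply(groups, function(gr) which(x$subpop == gr))
  # per-pop per-SNP: sample size, alt frequency, het frequency
  percol <- function(f) vapply(idx, f, numeric(ncol(g)))
  as_mat <- function(m) if (is.matrix(m)) m else matrix(m, nrow = 1)
  n_i <- as_mat(percol(function(ii) colSums(!is.na(g[ii, , drop = FALSE]))))
  p_i <- as_mat(percol(function(ii)
    colSums(g[ii, , drop = FALSE], na.rm = TRUE))) / (2 * pmax(n_i, 1))
  h_i <- as_mat(percol(function(ii)
    colSums(g[ii, , drop = FALSE] == 1, na.rm = TRUE))) / pmax(n_i, 1)

  r <- 2
  nbar <- rowMeans(n_i)
  valid <- n_i[, 1] >= 2 & n_i[, 2] >= 2
  nc <- (r * nbar - rowSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_i * p_i) / (r * nbar)
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / (r * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(valid & abs(denom) > 0, a / denom, NA_real_)
  theta[pbar %in% c(0, 1)] <- NA_real_          # monomorphic across both pops
  pmin(pmax(theta, 0), 1)
}

#' Garud H1 and H12 haplotype homozygosity
#'
#' Slides a window of `h_window` consecutive SNPs (step `h_step`) along each
#' chromosome; within each window, haplotype frequencies `p1 >= p2 >= ...`
#' are computed over full window strings (haplotypes with any missing allele
#' in the window are excluded). H1 = sum(p_i^2); H12 pools the two most
#' frequent classes: (p1 + p2)^2 + sum_{i>=3} p_i^2. The window value is
#' assigned to the SNP at 0-based offset `floor(h_window / 2)`; SNPs that
#' receive no window are `NA`. A chromosome shorter than the window is all
#' `NA` (with a warning).
#'
#' @param x a `hapmat`.
#' @param h_window,h_step window size and step in SNPs.
#' @return data frame with per-SNP columns `h1` and `h12`.
#' @export
haplotype_homozygosity <- function(x, h_window = 14L, h_step = 1L) {
  w <- as.integer(h_window); step <- as.integer(h_step)
  L <- n_loci(x)
  h1 <- rep(NA_real_, L); h12 <- rep(NA_real_, L)
  A <- x$alleles
  for (chr in unique(x$map$chrom)) {
    cols <- which(x$map$chrom == chr)
    if (length(cols) < w) {
      warning("chromosome ", chr, " has fewer than ", w, " SNPs; H1/H12 NA")
      next
    }
    Ac <- A[, cols, drop = FALSE]
    miss <- is.na(Ac)
    A0 <- Ac; A0[miss] <- 0L
    starts <- seq(1L, length(cols) - w + 1L, by = step)
    pow <- 2^(seq_len(w) - 1)
    # rolling window code per haplotype plus rolling missing count
    code <- as.vector(A0[, 1:w, drop = FALSE] %*% pow)
    nmiss <- rowSums(miss[, 1:w, drop = FALSE])
    prev <- 1L
    for (s in starts) {
      while (prev < s) {  # advance the rolling window by one SNP
        code <- (code - A0[, prev]) / 2 + A0[, prev + w] * pow[w]
        nmiss <- nmiss - miss[, prev] + miss[, prev + w]
        prev <- prev + 1L
      }
      ok <- nmiss == 0
      if (!any(ok)) next
      cnt <- tabulate(match(code[ok], unique(code[ok])))
      p <- sort(cnt / sum(cnt), decreasing = TRUE)
      H1 <- sum(p^2)
      H12 <- if (length(p) >= 2) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else H1
      target <- cols[s + w %/% 2L]
      h1[target] <- H1
      h12[target] <- H12
    }
  }
  data.frame(h1 = h1, h12 = h12)
}

# Tajima (1989) normalising constants for n sampled haplotypes
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Binned Tajima's D
#'
#' Each chromosome is partitioned into non-overlapping bins of
#' `tajima_bin_bp`; per bin, D is computed from the segregating-site count S
#' and the mean pairwise difference, with the standard normalising constants
#' for the haplotype sample size. The bin value is assigned to every SNP in
#' the bin; bins with S = 0 are set to 0 (missing values are converted to
#' zero downstream of every statistic).
#'
#' @param x a `hapmat` with at least 4 haplotypes.
#' @param tajima_bin_bp bin width in bp.
#' @return numeric vector of per-SNP D values.
#' @export
tajimas_d <- function(x, tajima_bin_bp = 300000L) {
  nhap <- nrow(x$alleles)
  if (nhap < 4) stop("Tajima's D needs at least 4 haplotypes")
  k <- tajima_constants(nhap)
  d <- rep(0, n_loci(x))
  bin <- paste(x$map$chrom, (x$map$pos - 1L) %/% as.integer(tajima_bin_bp))
  A <- x$alleles
  for (b in unique(bin)) {
    cols <- which(bin == b)
    n_s <- colSums(!is.na(A[, cols, drop = FALSE]))
    j <- colSums(A[, cols, drop = FALSE], na.rm = TRUE)
    seg <- n_s >= 2 & j > 0 & j < n_s
    S <- sum(seg)
    if (S == 0) { d[cols] <- 0; next }
    # mean pairwise difference summed over sites, each at its own call count
    pi_site <- ifelse(seg, 2 * j * (n_s - j) / pmax(n_s * (n_s - 1), 1), 0)
    k_hat <- sum(pi_site)
    d[cols] <- (k_hat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  d
}

#' Per-site nucleotide diversity
#'
#' pi = 2 j (n - j) / (n (n - 1)) with j the alternate-allele count among the
#' n non-missing alleles at the site; `NA` where fewer than 2 alleles are
#' called.
#'
#' @param x a `hapmat`.
#' @return numeric vector of per-SNP pi.
#' @export
site_pi <- function(x) {
  A <- x$alleles
  n <- colSums(!is.na(A))
  j <- colSums(A, na.rm = TRUE)
  ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
}

#' Running-median smoothing with constant end rule
#'
#' Centred running median of width `smooth_k` within each chromosome; the
#' first and last `floor(smooth_k / 2)` positions copy the nearest fully
#' windowed median. Missing values are imputed as 0 before smoothing (the
#' pipeline's convention for all missing statistic values). On a chromosome
#' shorter than `smooth_k` the largest odd width that fits is used.
#'
#' @param values per-SNP numeric vector.
#' @param chrom chromosome of each SNP (same length), or `NULL` for a single
#'   series.
#' @param smooth_k odd window width in SNPs.
#' @return smoothed numeric vector.
#' @export
running_median <- function(values, chrom = NULL, smooth_k = 31L) {
  v <- values
  v[is.na(v)] <- 0
  if (is.null(chrom)) chrom <- rep(1L, length(v))
  out <- numeric(length(v))
  for (chr in unique(chrom)) {
    ii <- which(chrom == chr)
    n <- length(ii)
    k <- min(smooth_k, if (n %% 2 == 1) n else n - 1)
    if (k < 3) { out[ii] <- v[ii]; next }
    out[ii] <- stats::runmed(v[ii], k = k, endrule = "constant")
  }
  out
}

#' Compute the five-statistic panel
#'
#' Raw and smoothed layers of FST, H1, H12, Tajima's D and per-site pi for
#' every SNP, with the tail direction of each statistic attached (right tail
#' for FST/H1/H12 — sweeps push them up; left tail for Tajima's D and pi —
#' sweeps push them down).
#'
#' @param x a `hapmat` with two subpopulation labels.
#' @param wcfg a [window_config()].
#' @return data frame: map columns, `fst`, `h1`, `h12`, `tajima_d`, `pi` and
#'   their `*_sm` smoothed layers; attribute `tails` names each statistic's
#'   tail.
#' @export
compute_stat_panel <- function(x, wcfg = window_config()) {
  hh <- haplotype_homozygosity(x, wcfg$h_window, wcfg$h_step)
  panel <- data.frame(
    chrom = x$map$chrom, pos = x$map$pos, id = x$map$id,
    fst = weir_cockerham_fst(x),
    h1 = hh$h1, h12 = hh$h12,
    tajima_d = tajimas_d(x, wcfg$tajima_bin_bp),
    pi = site_pi(x),
    stringsAsFactors = FALSE)
  for (s in stat_names()) {
    panel[[paste0(s, "_sm")]] <-
      running_median(panel[[s]], panel$chrom, wcfg$smooth_k)
  }
  attr(panel, "tails") <- stat_tails()
  panel
}

stat_names <- function() c("fst", "h1", "h12", "tajima_d", "pi")

stat_tails <- function() {
  c(fst = "right", h1 = "right", h12 = "right",
    tajima_d = "left", pi = "left")
}
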