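# Independent brute-force oracles. Deliberately naive: direct loops and
# closed-form evaluation, sharing no code with the package implementations.

# mean pairwise difference at one site by explicit pair enumeration
oracle_site_pi <- function(alleles) {
  a <- alleles[!is.na(alleles)]
  n <- length(a)
  if (n < 2) return(NA_real_)
  diffs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) diffs <- diffs + (a[i] != a[j])
  diffs / choose(n, 2)
}

# Tajima's D for one bin (matrix haplotypes x sites), direct formula
oracle_tajima_d <- function(m) {
  n <- nrow(m)
  seg <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    length(col) >= 2 && length(unique(col)) > 1
  })
  S <- sum(seg)
  if (S == 0) return(0)
  k_hat <- sum(sapply(which(seg), function(j) oracle_site_pi(m[, j])))
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# H1/H12 for one window by string pasting
oracle_h1h12 <- function(window) {
  keep <- apply(window, 1, function(h) !any(is.na(h)))
  strs <- apply(window[keep, , drop = FALSE], 1, paste, collapse = "")
  p <- sort(as.vector(table(strs)) / length(strs), decreasing = TRUE)
  h1 <- sum(p^2)
  h12 <- if (length(p) >= 2) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else h1
  c(h1 = h1, h12 = h12)
}

# Weir-Cockerham (1984) theta for one SNP, two populations, from genotype
# vectors (dosage 0/1/2 with NA), written straight off the variance
# components
oracle_wc_fst <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2); r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  max(0, min(1, a / (a + b + cc)))
}

# fractional-rank p-values via explicit tie-averaged ranks
oracle_frac_p <- function(v, tail) {
  n <- length(v)
  r <- sapply(seq_len(n), function(i) {
    sum(v < v[i]) + (1 + sum(v == v[i])) / 2
  })
  left <- r / (n + 1)
  right <- (n + 1 - r) / (n + 1)
  if (tail == "left") left
  else if (tail == "right") right
  else pmin(2 * pmin(left, right), n / (n + 1))
}

# BH step-up by the literal definition q_(i) = min_{j>=i} p_(j) n / j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[o[i]] <- min(sapply(i:n, function(j) p[o[j]] * n / j), 1)
  }
  q
}

# exact HWE p by the Wigginton-style recurrence over het counts
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na_ <- 2 * n_aa + n_Aa
  rare <- min(nA, na_)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  if (length(hets) > 1) {
    for (k in 1:(length(hets) - 1)) {
      h <- hets[k]
      # P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2)(h+1))
      nAAh <- (nA - h) / 2
      naah <- (na_ - h) / 2
      pr[k + 1] <- pr[k] * 4 * nAAh * naah / ((h + 2) * (h + 1))
    }
  }
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# interval overlap by double loop
oracle_overlap <- function(regions, features) {
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(features))) {
      if (regions$chrom[i] == features$chrom[j] &&
          regions$start_pos[i] <= features$end[j] &&
          features$start[j] <= regions$end_pos[i]) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), ncol = 2))
  do.call(rbind, hits)
}
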