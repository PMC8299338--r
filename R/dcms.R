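#' Fractional-rank p-values
#'
#' Converts a statistic track to empirical p-values from fractional
#' (average-on-ties) ranks. With ascending ranks `r` in `[1, n]`: left tail
#' `p = r/(n+1)`, right tail `p = (n+1-r)/(n+1)`, two-sided
#' `p = 2 min(left, right)` capped at `n/(n+1)`. All p-values are bounded
#' inside `[1/(n+1), n/(n+1)]`, so downstream logits are always finite.
#'
#' @param values finite numeric vector (missing values must already be
#'   imputed, by convention to 0).
#' @param tail one of `"left"`, `"right"`, `"two"`.
#' @return numeric vector of p-values.
#' @export
fractional_rank_pvalues <- function(values, tail = c("right", "left", "two")) {
  tail <- match.arg(tail)
  n <- length(values)
  if (n == 0) stop("empty value vector")
  if (any(!is.finite(values))) stop("values must be finite (impute missing first)")
  r <- rank(values, ties.method = "average")
  left <- r / (n + 1)
  right <- (n + 1 - r) / (n + 1)
  switch(tail,
         left = left,
         right = right,
         two = pmin(2 * pmin(left, right), n / (n + 1)))
}

#' Robust correlation matrix of the statistic panel (MCD)
#'
#' Minimum Covariance Determinant estimate of the 5 x 5 correlation between
#' the statistics: the covariance of the `h = ceiling(alpha * n)`-subset with
#' the smallest covariance determinant (found by seeded random subset search
#' with `nsamp` candidate subsets), converted to a correlation matrix. If the
#' best subset is singular the classical correlation is returned with a
#' warning.
#'
#' @param stats numeric matrix, loci in rows, statistics in columns.
#' @param alpha subset fraction retained by MCD (default 0.75).
#' @param nsamp number of candidate subsets (default 50,000).
#' @param seed integer seed making the subset search reproducible.
#' @return correlation matrix with attributes `alpha`, `nsamp`, `seed`,
#'   `estimator`.
#' @export
robust_correlation_mcd <- function(stats, alpha = 0.75, nsamp = 50000L,
                                   seed = 1L) {
  X <- as.matrix(stats)
  if (nrow(X) < 20) stop("need at least 20 loci for a stable MCD estimate")
  h <- ceiling(alpha * nrow(X))
  est <- "mcd"
  R <- tryCatch({
    cv <- withr::with_seed(seed,
      MASS::cov.rob(X, method = "mcd", quantile.used = h, nsamp = nsamp))
    stats::cov2cor(cv$cov)
  }, error = function(e) {
    warning("MCD failed (", conditionMessage(e),
            "); falling back to classical correlation")
    est <<- "classical"
    stats::cor(X)
  })
  if (any(!is.finite(R))) {
    warning("singular MCD covariance; falling back to classical correlation")
    est <- "classical"
    R <- stats::cor(X)
  }
  structure(R, alpha = alpha, nsamp = nsamp, seed = seed, estimator = est)
}

#' Combine p-values into the DCMS composite
#'
#' For locus `l` with per-statistic p-values `p_lt`,
#' `DCMS_l = sum_t w_t * log((1 - p_lt) / p_lt)` where the de-correlation
#' weight of statistic `t` is `w_t = 1 / sum_i |r_it|` (the sum runs over all
#' statistics including `t` itself), so a statistic highly correlated with
#' the others contributes less. With an identity correlation the composite is
#' the plain sum of logits; with all statistics perfectly correlated it
#' collapses to the mean logit.
#'
#' @param pvals matrix of p-values, loci in rows, statistics in columns; all
#'   strictly inside (0, 1).
#' @param corr correlation matrix of the statistics (columns of `pvals`).
#' @return numeric vector of per-locus DCMS values.
#' @export
dcms_combine <- function(pvals, corr) {
  P <- as.matrix(pvals)
  if (ncol(P) != ncol(corr)) stop("p-value and correlation dimensions disagree")
  if (any(P <= 0 | P >= 1)) stop("all p-values must lie strictly in (0, 1)")
  w <- 1 / colSums(abs(corr))
  if (any(w <= 0) || any(!is.finite(w))) stop("non-positive de-correlation weight")
  as.vector(log((1 - P) / P) %*% w)
}

#' Robust normal fit of the DCMS distribution
#'
#' Location by an intercept-only Huber M-estimate (tuning constant
#' `c = 1.345`, iterated to relative tolerance 1e-8); scale by the
#' normalised median absolute deviation. Resistant to the sweep-induced
#' right tail, so the fitted null describes the genome-wide bulk.
#'
#' @param x numeric vector of composite values (>= 30).
#' @param k Huber tuning constant.
#' @return list with `mu` and `sigma`.
#' @export
robust_normal_fit <- function(x, k = 1.345) {
  x <- x[is.finite(x)]
  if (length(x) < 30) stop("need at least 30 values")
  sigma <- stats::mad(x)
  if (sigma <= 0) stop("zero spread: scale is not estimable")
  mu <- stats::median(x)
  for (it in 1:200) {
    u <- (x - mu) / sigma
    w <- pmin(1, k / pmax(abs(u), 1e-300))
    mu_new <- sum(w * x) / sum(w)
    if (abs(mu_new - mu) <= 1e-8 * max(1, abs(mu))) { mu <- mu_new; break }
    mu <- mu_new
  }
  list(mu = mu, sigma = sigma)
}

#' Upper-tail normal p-values for DCMS
#'
#' @param dcms numeric vector of composite values.
#' @param mu,sigma the robust normal fit.
#' @return `1 - Phi((dcms - mu) / sigma)`.
#' @export
upper_tail_p <- function(dcms, mu, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  stats::pnorm(dcms, mean = mu, sd = sigma, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_qvalues <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Full DCMS track from a statistic panel
#'
#' Ranks the smoothed layer of each statistic with its tail direction,
#' estimates the robust correlation on the smoothed statistics, combines into
#' DCMS, fits the robust normal and returns per-SNP p- and q-values.
#' Missing smoothed values have already been imputed to 0 by the smoother.
#'
#' @param panel output of [compute_stat_panel()].
#' @param alpha,nsamp,seed MCD parameters (see [robust_correlation_mcd()]).
#' @return list: `track` data frame (`dcms`, `p`, `q`), `pvals` matrix,
#'   `corr`, `fit`.
#' @export
dcms_track <- function(panel, alpha = 0.75, nsamp = 50000L, seed = 1L) {
  tails <- stat_tails()
  sm <- as.matrix(panel[paste0(names(tails), "_sm")])
  colnames(sm) <- names(tails)
  P <- sapply(names(tails), function(s)
    fractional_rank_pvalues(sm[, s], tails[[s]]))
  corr <- robust_correlation_mcd(sm, alpha = alpha, nsamp = nsamp, seed = seed)
  dcms <- dcms_combine(P, corr)
  fit <- robust_normal_fit(dcms)
  p <- upper_tail_p(dcms, fit$mu, fit$sigma)
  q <- bh_qvalues(p)
  list(track = data.frame(dcms = dcms, p = p, q = q),
       pvals = P, corr = corr, fit = fit)
}
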