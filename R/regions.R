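#' Region-calling configuration
#'
#' A region is a maximal run of consecutive SNPs with `q <= boundary_q` that
#' contains at least `core_min` consecutive SNPs with `q < sig_q`: the core
#' marks significance, the looser boundary threshold extends the interval to
#' the last SNP before the signal decays past q = 0.1.
#'
#' @param sig_q core significance threshold (default 0.05).
#' @param boundary_q boundary threshold (default 0.1).
#' @param core_min consecutive significant SNPs required (default 2; can be
#'   lowered to 1 to admit single-SNP peaks).
#' @return a `region_config` list.
#' @export
region_config <- function(sig_q = 0.05, boundary_q = 0.1, core_min = 2L) {
  if (sig_q > boundary_q) stop("sig_q must not exceed boundary_q")
  if (core_min < 1) stop("core_min must be >= 1")
  structure(list(sig_q = sig_q, boundary_q = boundary_q,
                 core_min = as.integer(core_min)),
            class = "region_config")
}

#' Call significant genomic regions from the q-value track
#'
#' @param scan data frame with columns `chrom`, `pos`, `q`, position-sorted
#'   within chromosome.
#' @param cfg a [region_config()].
#' @return data frame of regions: `chrom`, `start_pos`, `end_pos` (1-based
#'   inclusive bp of the first/last member SNP), `n_snps`, `peak_q`,
#'   `peak_pos`.
#' @export
call_regions <- function(scan, cfg = region_config()) {
  out <- list()
  for (chr in unique(scan$chrom)) {
    s <- scan[scan$chrom == chr, , drop = FALSE]
    if (any(diff(s$pos) <= 0)) stop("positions not sorted on chromosome ", chr)
    inb <- s$q <= cfg$boundary_q
    if (!any(inb)) next
    r <- rle(inb)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      ii <- starts[k]:ends[k]
      # core: longest run of consecutive SNPs below sig_q inside the window
      sig <- s$q[ii] < cfg$sig_q
      core_len <- if (any(sig)) max(rle(sig)$lengths[rle(sig)$values]) else 0L
      if (core_len < cfg$core_min) next
      qq <- s$q[ii]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start_pos = s$pos[ii[1]], end_pos = s$pos[ii[length(ii)]],
        n_snps = length(ii), peak_q = min(qq),
        peak_pos = s$pos[ii[which.min(qq)]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), n_snps = integer(),
                      peak_q = numeric(), peak_pos = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarise called regions
#'
#' One row in the style of a genome-scan summary table: region count,
#' mean +/- SD length in kb (sample SD; a single region reports SD 0),
#' minimum length in kb, maximum length in Mb, total member SNPs and total
#' spanned size in Mb. Region length is the member-SNP span,
#' `end - start + 1` bp.
#'
#' @param regions data frame from [call_regions()].
#' @return one-row data frame.
#' @export
summarize_regions <- function(regions) {
  n <- nrow(regions)
  if (n == 0)
    return(data.frame(n_regions = 0L, mean_kb = 0, sd_kb = 0, min_kb = 0,
                      max_mb = 0, n_snps = 0L, total_mb = 0))
  len_bp <- regions$end_pos - regions$start_pos + 1
  data.frame(
    n_regions = n,
    mean_kb = mean(len_bp) / 1000,
    sd_kb = if (n > 1) stats::sd(len_bp) / 1000 else 0,
    min_kb = min(len_bp) / 1000,
    max_mb = max(len_bp) / 1e6,
    n_snps = sum(regions$n_snps),
    total_mb = sum(len_bp) / 1e6)
}
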