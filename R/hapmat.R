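#' Phased haplotype matrix
#'
#' The central container of the package: a `2 * n_samples x n_loci` integer
#' matrix of phased alleles (0 = reference, 1 = alternate, `NA` = missing),
#' together with a variant map and optional per-sample subpopulation labels.
#' Rows `2i - 1` and `2i` are the two haplotypes of sample `i`.
#'
#' @param alleles integer matrix, `2 * n_samples` rows by `n_loci` columns;
#'   entries 0, 1 or `NA`.
#' @param map data frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt`; one row per locus, sorted by (chrom, pos).
#' @param sample_ids character vector of sample identifiers.
#' @param subpop optional character vector of subpopulation labels, one per
#'   sample (e.g. `"founder"` / `"farmborn"`), or `NULL`.
#' @return An object of class `hapmat`.
#' @export
hap_matrix <- function(alleles, map, sample_ids, subpop = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype count must be even (2 per sample)")
  n <- nrow(alleles) / 2L
  if (length(sample_ids) != n)
    stop("expected ", n, " sample ids, got ", length(sample_ids))
  if (!is.null(subpop) && length(subpop) != n)
    stop("subpop labels must have one entry per sample")
  map <- validate_variant_map(map)
  if (nrow(map) != ncol(alleles))
    stop("map has ", nrow(map), " rows but matrix has ", ncol(alleles), " loci")
  ok <- alleles %in% c(0L, 1L, NA_integer_)
  if (!all(ok)) stop("alleles must be 0, 1 or NA")
  structure(
    list(alleles = alleles, map = map,
         sample_ids = as.character(sample_ids),
         subpop = if (is.null(subpop)) NULL else as.character(subpop)),
    class = "hapmat")
}

#' @export
print.hapmat <- function(x, ...) {
  cat("hapmat: ", n_samples(x), " samples (", nrow(x$alleles), " haplotypes), ",
      n_loci(x), " loci on ", length(unique(x$map$chrom)), " chromosome(s)\n",
      sep = "")
  if (!is.null(x$subpop)) {
    tab <- table(x$subpop)
    cat("subpopulations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname hap_matrix
#' @param x a `hapmat`.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname hap_matrix
#' @export
n_loci <- function(x) nrow(x$map)

#' Validate and normalise a variant map
#'
#' Checks the invariants the pipeline relies on: required columns, strictly
#' increasing positions within each chromosome after sorting, biallelic
#' single-nucleotide ref/alt.
#'
#' @param map data frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @return The map, column types normalised.
#' @export
validate_variant_map <- function(map) {
  need <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("map lacks column(s): ", paste(miss, collapse = ", "))
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  map$id <- as.character(map$id)
  map$ref <- as.character(map$ref)
  map$alt <- as.character(map$alt)
  # duplicates are representable (QC removes them); order must be sorted
  for (chr in unique(map$chrom)) {
    p <- map$pos[map$chrom == chr]
    if (any(diff(p) < 0))
      stop("positions not sorted on chromosome ", chr)
  }
  rownames(map) <- NULL
  map[need]
}

#' Subset a haplotype matrix
#'
#' @param x a `hapmat`.
#' @param loci integer or logical index over loci (default all).
#' @param samples integer or logical index over samples (default all).
#' @return a `hapmat` restricted to the selected loci and samples.
#' @export
subset_hapmat <- function(x, loci = NULL, samples = NULL) {
  a <- x$alleles; map <- x$map; sid <- x$sample_ids; sp <- x$subpop
  if (!is.null(loci)) {
    a <- a[, loci, drop = FALSE]
    map <- map[loci, , drop = FALSE]
  }
  if (!is.null(samples)) {
    idx <- seq_along(sid)[samples]
    hap_rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    a <- a[hap_rows, , drop = FALSE]
    sid <- sid[idx]
    if (!is.null(sp)) sp <- sp[idx]
  }
  hap_matrix(a, map, sid, sp)
}

#' Diploid genotype dosages
#'
#' Collapses the haplotype matrix to an `n_samples x n_loci` matrix of
#' alternate-allele dosages (0/1/2); a genotype is `NA` if either haplotype
#' allele is missing.
#'
#' @param x a `hapmat`.
#' @return integer matrix of dosages.
#' @export
genotype_dosage <- function(x) {
  n <- n_samples(x)
  a1 <- x$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- x$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  g <- a1 + a2
  rownames(g) <- x$sample_ids
  g
}

# natural chromosome order: numeric where parseable (chr prefix stripped),
# non-numeric names after, lexicographically
chrom_order_key <- function(chrom) {
  chrom <- as.character(chrom)
  stripped <- sub("^[Cc]hr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  order(is.na(num), num, chrom)
}

sort_chrom_levels <- function(chrom) {
  u <- unique(as.character(chrom))
  u[chrom_order_key(u)]
}

#' Derive a stage seed from the global pipeline seed
#'
#' Every stochastic stage uses `(seed + 999983 * k) mod (2^31 - 1)` with `k`
#' the stage's fixed index, so a stage rerun in isolation reproduces the
#' full-run result.
#'
#' @param seed global integer seed.
#' @param stage one of `"simulate"`, `"split"`, `"mcd"`, `"enrich"`, `"qc"`.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, split = 2L, mcd = 3L, enrich = 4L, qc = 5L)
  k <- stages[[stage]]
  as.integer((as.numeric(seed) + 999983 * k) %% 2147483647)
}
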