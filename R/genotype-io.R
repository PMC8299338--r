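#' Read phased genotypes from a VCF
#'
#' Loads a VCF with phased GT fields into a [hap_matrix()]. Multiallelic and
#' non-SNP records are skipped (a message reports the count); retained
#' records must be phased (`|` separator) — an unphased genotype is an error
#' naming the offending record. Records are sorted by (chromosome, position)
#' with natural chromosome order; samples are never reordered.
#'
#' @param path path to a VCF 4.x file (plain text or gzipped).
#' @param subpop_table optional data frame with columns `sample` and `subpop`
#'   assigning every sample in the VCF a subpopulation label.
#' @return a `hapmat`.
#' @export
read_phased_vcf <- function(path, subpop_table = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message("skipped ", n_skip, " multiallelic/non-SNP record(s)")
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]

  unphased <- grepl("/", gt) & !is.na(gt)
  if (any(unphased)) {
    i <- which(rowSums(unphased) > 0)[1]
    stop("unphased genotype at record ", fix$CHROM[i], ":", fix$POS[i],
         " (", fix$ID[i], ")")
  }

  samples <- colnames(gt)
  subpop <- NULL
  if (!is.null(subpop_table)) {
    if (!all(c("sample", "subpop") %in% names(subpop_table)))
      stop("subpop_table needs columns 'sample' and 'subpop'")
    m <- match(samples, subpop_table$sample)
    if (anyNA(m))
      stop("samples missing from subpop_table: ",
           paste(samples[is.na(m)], collapse = ", "))
    subpop <- as.character(subpop_table$subpop[m])
  }

  # split "a|b" into two haplotype alleles; "." -> NA
  parse_allele <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out[!x %in% c("0", "1")] <- NA_integer_
    out
  }
  a1 <- parse_allele(sub("\\|.*$", "", gt))
  a2 <- parse_allele(sub("^.*\\|", "", gt))
  nl <- nrow(fix); ns <- length(samples)
  alleles <- matrix(NA_integer_, nrow = 2L * ns, ncol = nl)
  alleles[seq(1L, 2L * ns, by = 2L), ] <- t(matrix(a1, nrow = nl))
  alleles[seq(2L, 2L * ns, by = 2L), ] <- t(matrix(a2, nrow = nl))

  map <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                paste0(fix$CHROM, "_", fix$POS), fix$ID),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  lev <- sort_chrom_levels(map$chrom)
  o <- order(match(map$chrom, lev), map$pos)
  hap_matrix(alleles[, o, drop = FALSE], map[o, , drop = FALSE], samples, subpop)
}

#' Write a haplotype matrix as a minimal phased VCF
#'
#' Emits a GT-only VCF 4.2 file that [read_phased_vcf()] reads back with
#' exact allele equality. Missing alleles are written as `.`.
#'
#' @param x a `hapmat`.
#' @param path output path (plain text).
#' @export
write_phased_vcf <- function(x, path) {
  n <- n_samples(x)
  a1 <- x$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- x$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  f <- function(a) { s <- as.character(a); s[is.na(a)] <- "."; s }
  gt <- matrix(paste0(f(a1), "|", f(a2)), nrow = n)  # samples x loci
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$sample_ids), collapse = "\t"))
  body <- paste(x$map$chrom, x$map$pos, x$map$id, x$map$ref, x$map$alt,
                ".", ".", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write the haplotype-matrix TSV fixture format
#'
#' A plain-text round-trippable representation: `<path>` holds a header row
#' of locus ids and one row per haplotype (sample id + haplotype index in the
#' first two columns), and the side-car `<path>.map` holds the variant map.
#'
#' @param path path of the haplotype TSV (the map is `<path>.map`).
#' @return a `hapmat`.
#' @export
read_haplotype_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("haplotype TSV has no data rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  nfield <- length(header)
  for (i in seq_along(parts)[-1]) {
    if (length(parts[[i]]) != nfield)
      stop("ragged row ", i - 1L, ": ", length(parts[[i]]),
           " fields, expected ", nfield)
  }
  body <- do.call(rbind, parts[-1])
  sample_ids <- unique(body[, 1])
  a <- body[, -(1:2), drop = FALSE]
  a[a == "NA" | a == "."] <- NA
  alleles <- matrix(as.integer(a), nrow = nrow(a))
  map <- utils::read.delim(paste0(path, ".map"), colClasses = "character")
  map$pos <- as.integer(map$pos)
  hap_matrix(alleles, map, sample_ids)
}

#' @rdname read_haplotype_tsv
#' @param x a `hapmat` to write.
#' @export
write_haplotype_tsv <- function(x, path) {
  n <- n_samples(x)
  a <- x$alleles
  a_chr <- matrix(as.character(a), nrow = nrow(a))
  a_chr[is.na(a)] <- "NA"
  rows <- apply(a_chr, 1, paste, collapse = "\t")
  sid <- rep(x$sample_ids, each = 2L)
  hapix <- rep(c("1", "2"), times = n)
  header <- paste(c("sample", "hap", x$map$id), collapse = "\t")
  writeLines(c(header, paste(sid, hapix, rows, sep = "\t")), path)
  utils::write.table(x$map, paste0(path, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-SNP scan table
#'
#' One row per SNP: chromosome, position, id, the five raw statistics, their
#' smoothed layers, the five fractional-rank p-values, DCMS, its normal-fit
#' p-value and BH q-value.
#'
#' @param scan data frame as produced by [run_scan()].
#' @param path output TSV path.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called regions as BED
#'
#' BED is 0-based half-open, so a region whose member SNPs span 1-based
#' positions `[start, end]` is written as `start-1  end`. The name column is
#' the region id and the score column the peak q-value.
#'
#' @param regions data frame from [call_regions()].
#' @param path output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- "#chrom\tstart\tend\tname\tpeak_q"
  if (nrow(regions) > 0) {
    lev <- sort_chrom_levels(regions$chrom)
    o <- order(match(regions$chrom, lev), regions$start_pos)
    r <- regions[o, , drop = FALSE]
    lines <- c(lines, paste(r$chrom, r$start_pos - 1L, r$end_pos,
                            sprintf("region_%03d", seq_len(nrow(r))),
                            signif(r$peak_q, 6), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
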