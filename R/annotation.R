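#' QTL trait classes recognised by the enrichment tables
#' @export
qtl_classes <- function() {
  c("Milk", "Production", "Exterior", "Reproduction", "Health",
    "Meat_and_Carcass")
}

# drop non-comment lines with the wrong field count before handing the file
# to rtracklayer (which errors hard on ragged rows); returns path + skip count
prefilter_gff_lines <- function(path, nfields = 9L) {
  lines <- readLines(path)
  data_rows <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- data_rows & nf != nfields
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    tmp <- tempfile(fileext = paste0(".", tools::file_ext(path)))
    writeLines(lines[!bad], tmp)
    path <- tmp
  }
  list(path = path, n_skipped = n_skipped)
}

#' Parse gene annotation from GTF
#'
#' Reads gene-level rows (feature type `gene`) into a feature table with
#' 1-based inclusive coordinates. Malformed rows are skipped and counted.
#'
#' @param path GTF file path.
#' @return data frame: `chrom`, `start`, `end`, `kind` (= "gene"), `name`;
#'   attribute `n_skipped` counts dropped rows.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  pf <- prefilter_gff_lines(path)
  gr <- rtracklayer::import(pf$path, format = "gtf")
  gr <- gr[as.character(gr$type) == "gene"]
  md <- S4Vectors::mcols(gr)
  name <- if ("gene_name" %in% names(md) && !all(is.na(md$gene_name)))
    as.character(md$gene_name) else as.character(md$gene_id)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    kind = rep("gene", length(gr)), name = name, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- pf$n_skipped
  out
}

#' Parse QTL annotation from an Animal-QTLdb-style GFF
#'
#' Expects GFF3 rows carrying `trait` and `qtl_class` attributes (and a
#' `Name`). Rows without a trait are skipped and counted; classes outside
#' [qtl_classes()] are mapped to `"Other"` with a warning.
#'
#' @param path GFF3 file path.
#' @return data frame: `chrom`, `start`, `end`, `kind` (= "QTL"), `name`,
#'   `trait`, `qtl_class`; attribute `n_skipped`.
#' @export
parse_qtl_gff <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  pf <- prefilter_gff_lines(path)
  gr <- rtracklayer::import(pf$path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  trait <- if ("trait" %in% names(md)) as.character(md$trait)
           else rep(NA_character_, length(gr))
  keep <- !is.na(trait) & nzchar(trait)
  n_skipped <- pf$n_skipped + sum(!keep)
  gr <- gr[keep]; md <- S4Vectors::mcols(gr); trait <- trait[keep]
  cls <- if ("qtl_class" %in% names(md)) as.character(md$qtl_class)
         else rep(NA_character_, length(gr))
  unknown <- is.na(cls) | !(cls %in% qtl_classes())
  if (any(unknown)) {
    warning(sum(unknown), " QTL record(s) with unknown class mapped to 'Other'")
    cls[unknown] <- "Other"
  }
  name <- if ("Name" %in% names(md)) as.character(md$Name)
          else sprintf("QTL_%d", seq_len(length(gr)))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    kind = rep("QTL", length(gr)), name = name, trait = trait,
    qtl_class = cls,
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Intersect regions with annotation features
#'
#' A feature is reported for a region iff the two 1-based inclusive intervals
#' share at least 1 bp on the same chromosome. Output is deterministic:
#' sorted by (region, feature chrom, start, name).
#'
#' @param regions data frame from [call_regions()].
#' @param features data frame from [parse_gtf()] / [parse_qtl_gff()].
#' @return data frame pairing `region_idx` with the overlapping feature rows.
#' @export
overlap_features <- function(regions, features) {
  empty <- cbind(data.frame(region_idx = integer()),
                 features[0, , drop = FALSE])
  if (nrow(regions) == 0 || nrow(features) == 0) return(empty)
  unmatched <- setdiff(unique(regions$chrom), unique(features$chrom))
  if (length(unmatched))
    warning("region chromosome(s) absent from annotation: ",
            paste(unmatched, collapse = ", "))
  rg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start_pos, regions$end_pos))
  fg <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::findOverlaps(rg, fg)
  if (length(hits) == 0) return(empty)
  out <- cbind(data.frame(region_idx = S4Vectors::queryHits(hits)),
               features[S4Vectors::subjectHits(hits), , drop = FALSE])
  o <- order(out$region_idx, match(out$chrom, sort_chrom_levels(out$chrom)),
             out$start, out$name)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' QTL class proportions among annotated QTLs
#'
#' @param annotated data frame of annotated QTL records (with `qtl_class`).
#' @return data frame `qtl_class`, `n`, `percent` (sums to 100); empty when
#'   nothing is annotated.
#' @export
qtl_class_proportions <- function(annotated) {
  if (nrow(annotated) == 0)
    return(data.frame(qtl_class = character(), n = integer(),
                      percent = numeric()))
  tab <- table(annotated$qtl_class)
  out <- data.frame(qtl_class = names(tab), n = as.integer(tab),
                    percent = 100 * as.integer(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n, out$qtl_class), , drop = FALSE]
}

#' Chromosome-based bootstrap QTL enrichment
#'
#' For every (trait, chromosome) pair with the trait present among the
#' annotated QTLs or the chromosome's database records: the observed count is
#' the number of annotated QTLs of that trait on that chromosome; the null
#' draws, in each of `n_iter` iterations, the same number of records as were
#' annotated on that chromosome from the database restricted to that
#' chromosome (with replacement) and counts the trait. The empirical p-value
#' is add-one smoothed, `(1 + #{null >= observed}) / (n_iter + 1)`, and
#' Benjamini-Hochberg adjusted across all pairs.
#'
#' @param annotated data frame of annotated QTL records.
#' @param db full QTL database as from [parse_qtl_gff()].
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param fdr_max pairs with adjusted p at or below this are flagged.
#' @return data frame: `trait`, `chrom`, `n_db`, `observed`, `expected_mean`,
#'   `p_emp`, `p_fdr`, `enriched`.
#' @export
qtl_enrichment_bootstrap <- function(annotated, db, n_iter = 1000L, seed = 1L,
                                     fdr_max = 0.05) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (nrow(annotated) == 0)
    return(data.frame(trait = character(), chrom = character(),
                      n_db = integer(), observed = integer(),
                      expected_mean = numeric(), p_emp = numeric(),
                      p_fdr = numeric(), enriched = logical()))
  chroms <- sort_chrom_levels(unique(annotated$chrom))
  missing_db <- setdiff(chroms, unique(db$chrom))
  if (length(missing_db))
    stop("QTL database lacks chromosome(s): ",
         paste(missing_db, collapse = ", "))
  rows <- list()
  withr::with_seed(seed, {
    for (chr in chroms) {
      ann_c <- annotated[annotated$chrom == chr, , drop = FALSE]
      db_c <- db[db$chrom == chr, , drop = FALSE]
      n_c <- nrow(ann_c)
      traits <- sort(unique(c(ann_c$trait, db_c$trait)))
      # one resampling per chromosome, shared across its traits
      draws <- matrix(sample.int(nrow(db_c), n_iter * n_c, replace = TRUE),
                      nrow = n_iter)
      drawn_traits <- matrix(db_c$trait[draws], nrow = n_iter)
      for (tr in traits) {
        obs <- sum(ann_c$trait == tr)
        null_counts <- rowSums(drawn_traits == tr)
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, chrom = chr, n_db = sum(db_c$trait == tr),
          observed = obs, expected_mean = mean(null_counts),
          p_emp = (1 + sum(null_counts >= obs)) / (n_iter + 1),
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_qvalues(out$p_emp)
  out$enriched <- out$p_fdr <= fdr_max
  out
}
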