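#' Assemble and validate the full pipeline configuration
#'
#' One nested configuration drives every stage; unknown keys are rejected
#' and cross-field constraints (e.g. `sig_q <= boundary_q`) are checked
#' before any computation runs. The global `seed` deterministically derives
#' every stage seed, so a stage rerun in isolation reproduces the full-run
#' result.
#'
#' @param qc a [qc_config()].
#' @param window a [window_config()].
#' @param dcms list of MCD/fit parameters: `alpha` (0.75), `nsamp` (50000).
#' @param region a [region_config()].
#' @param enrichment list: `n_iter` (1000), `fdr_max` (0.05).
#' @param sim a [sweep_sim_config()] (used by simulation drivers).
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(qc = qc_config(), window = window_config(),
                            dcms = list(), region = region_config(),
                            enrichment = list(), sim = sweep_sim_config(),
                            seed = 1L) {
  dcms_defaults <- list(alpha = 0.75, nsamp = 50000L)
  bad <- setdiff(names(dcms), names(dcms_defaults))
  if (length(bad)) stop("unknown dcms key(s): ", paste(bad, collapse = ", "))
  dcms <- utils::modifyList(dcms_defaults, dcms)
  enr_defaults <- list(n_iter = 1000L, fdr_max = 0.05)
  bad <- setdiff(names(enrichment), names(enr_defaults))
  if (length(bad)) stop("unknown enrichment key(s): ",
                        paste(bad, collapse = ", "))
  enrichment <- utils::modifyList(enr_defaults, enrichment)
  stopifnot(inherits(qc, "qc_config"), inherits(window, "window_config"),
            inherits(region, "region_config"),
            inherits(sim, "sweep_sim_config"))
  structure(list(qc = qc, window = window, dcms = dcms, region = region,
                 enrichment = enrichment, sim = sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(verbose, ...) if (verbose) message("[dcmscan] ", ...)

#' Run the selection scan
#'
#' Fixed stage order: variant QC -> per-chromosome statistics -> running
#' median smoothing -> fractional-rank p-values -> robust MCD correlation ->
#' DCMS -> robust normal fit -> upper-tail p -> BH q. Identical input,
#' configuration and seed give identical output.
#'
#' @param x a `hapmat` with two subpopulation labels.
#' @param cfg a [pipeline_config()].
#' @param verbose log stage parameters and row counts (default TRUE).
#' @return list: `scan` (per-SNP data frame with map, raw and smoothed
#'   statistics, per-statistic p-values, `dcms`, `p`, `q`), `corr`, `fit`,
#'   `qc_report`, `hapmat` (post-QC).
#' @export
run_scan <- function(x, cfg = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_stage(verbose, "QC: call rate >= ", cfg$qc$min_call_rate,
            ", MAF >= ", cfg$qc$min_maf, ", HWE p >= ", cfg$qc$hwe_p_floor,
            ", PI_HAT <= ", cfg$qc$pihat_max)
  fv <- filter_variants(x, cfg$qc)
  log_stage(verbose, "QC kept ", fv$report$n_surviving, "/",
            fv$report$n_input, " variants")
  xq <- fv$hapmat

  log_stage(verbose, "statistics: H window ", cfg$window$h_window, " step ",
            cfg$window$h_step, ", Tajima bin ", cfg$window$tajima_bin_bp,
            " bp, runmed k ", cfg$window$smooth_k)
  panel <- compute_stat_panel(xq, cfg$window)

  log_stage(verbose, "DCMS: MCD alpha ", cfg$dcms$alpha, ", nsamp ",
            cfg$dcms$nsamp, ", seed ", derive_seed(cfg$seed, "mcd"))
  dt <- dcms_track(panel, alpha = cfg$dcms$alpha, nsamp = cfg$dcms$nsamp,
                   seed = derive_seed(cfg$seed, "mcd"))

  scan <- cbind(panel,
                stats::setNames(as.data.frame(dt$pvals),
                                paste0("p_", colnames(dt$pvals))),
                dt$track)
  attr(scan, "tails") <- attr(panel, "tails")
  log_stage(verbose, "scan: ", nrow(scan), " SNPs, mu ",
            signif(dt$fit$mu, 4), ", sigma ", signif(dt$fit$sigma, 4))
  list(scan = scan, corr = dt$corr, fit = dt$fit, qc_report = fv$report,
       hapmat = xq)
}

#' Run the full pipeline: scan, regions, annotation, enrichment
#'
#' @param x a `hapmat` with two subpopulation labels.
#' @param cfg a [pipeline_config()].
#' @param gtf_path gene annotation GTF (optional; `NULL` skips annotation).
#' @param qtl_gff_path QTL annotation GFF3 (optional).
#' @param outdir if non-NULL, all artifacts are written there (scan TSV,
#'   regions BED + summary TSV, annotation and enrichment TSVs).
#' @param verbose log stages.
#' @return list: everything from [run_scan()] plus `regions`,
#'   `region_summary`, and (when annotation files are given) `genes`,
#'   `qtls`, `gene_overlaps`, `qtl_overlaps`, `class_proportions`,
#'   `enrichment`.
#' @export
run_full <- function(x, cfg = pipeline_config(), gtf_path = NULL,
                     qtl_gff_path = NULL, outdir = NULL, verbose = TRUE) {
  res <- run_scan(x, cfg, verbose = verbose)
  regions <- call_regions(res$scan, cfg$region)
  log_stage(verbose, "regions: ", nrow(regions), " at q < ",
            cfg$region$sig_q, " (boundary ", cfg$region$boundary_q, ")")
  res$regions <- regions
  res$region_summary <- summarize_regions(regions)

  if (!is.null(gtf_path)) {
    if (!file.exists(gtf_path)) stop("gene annotation not found: ", gtf_path)
    res$genes <- parse_gtf(gtf_path)
    res$gene_overlaps <- overlap_features(regions, res$genes)
    log_stage(verbose, "genes overlapping regions: ",
              length(unique(res$gene_overlaps$name)))
  }
  if (!is.null(qtl_gff_path)) {
    if (!file.exists(qtl_gff_path)) stop("QTL annotation not found: ",
                                         qtl_gff_path)
    res$qtls <- parse_qtl_gff(qtl_gff_path)
    res$qtl_overlaps <- overlap_features(regions, res$qtls)
    res$class_proportions <- qtl_class_proportions(res$qtl_overlaps)
    res$enrichment <- qtl_enrichment_bootstrap(
      res$qtl_overlaps, res$qtls, n_iter = cfg$enrichment$n_iter,
      seed = derive_seed(cfg$seed, "enrich"),
      fdr_max = cfg$enrichment$fdr_max)
    log_stage(verbose, "enrichment: ", sum(res$enrichment$enriched),
              " (trait, chromosome) pair(s) at FDR <= ",
              cfg$enrichment$fdr_max)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_scan_tsv(res$scan, file.path(outdir, "scan.tsv"))
    write_regions_bed(regions, file.path(outdir, "regions.bed"))
    utils::write.table(res$region_summary,
                       file.path(outdir, "region_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in c("gene_overlaps", "qtl_overlaps", "class_proportions",
                 "enrichment")) {
      if (!is.null(res[[nm]]))
        utils::write.table(res[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  res
}

#' @useDynLib dcmscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
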