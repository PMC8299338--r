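# Fixtures are built in code at test time.

make_map <- function(n, chrom = "1", spacing = 1000L, start = 1000L) {
  data.frame(chrom = rep(chrom, length.out = n),
             pos = start + spacing * (seq_len(n) - 1L),
             id = paste0("s", seq_len(n)),
             ref = "A", alt = "C", stringsAsFactors = FALSE)
}

# random hapmat: n samples, L loci, uniform allele frequencies
random_hapmat <- function(n = 10, L = 50, chrom = "1", miss = 0, seed = 1) {
  withr::with_seed(seed, {
    freq <- runif(L, 0.1, 0.9)
    a <- matrix(rbinom(2 * n * L, 1, rep(freq, each = 2 * n)), nrow = 2 * n)
    if (miss > 0) a[runif(length(a)) < miss] <- NA
    hap_matrix(a, make_map(L, chrom = chrom), paste0("s", seq_len(n)))
  })
}

# small phased VCF text fixture; gts is a list: one character vector per
# record, e.g. c("0|1", "1|1")
write_tiny_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r)
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", ".", ".", "GT", r$gt),
          collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}

vcf_rec <- function(chrom, pos, id, ref, alt, gt) {
  list(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt, gt = gt)
}

# synthetic gene GTF
write_tiny_gtf <- function(path, genes) {
  lines <- vapply(seq_len(nrow(genes)), function(i)
    paste(genes$chrom[i], "test", "gene",
          sprintf("%d", as.integer(genes$start[i])),
          sprintf("%d", as.integer(genes$end[i])), ".", "+", ".",
          sprintf("gene_id \"%s\"; gene_name \"%s\";",
                  genes$name[i], genes$name[i]),
          sep = "\t"), character(1))
  writeLines(c("##gtf", lines), path)
  path
}

# synthetic Animal-QTLdb-style GFF3 with trait and qtl_class attributes
write_tiny_qtl_gff <- function(path, qtls) {
  lines <- vapply(seq_len(nrow(qtls)), function(i) {
    attrs <- sprintf("ID=q%d;Name=%s", i, qtls$name[i])
    if (!is.na(qtls$trait[i]))
      attrs <- paste0(attrs, ";trait=", qtls$trait[i])
    if (!is.null(qtls$qtl_class) && !is.na(qtls$qtl_class[i]))
      attrs <- paste0(attrs, ";qtl_class=", qtls$qtl_class[i])
    paste(qtls$chrom[i], "QTLdb", "QTL",
          sprintf("%d", as.integer(qtls$start[i])),
          sprintf("%d", as.integer(qtls$end[i])),
          ".", ".", ".", attrs, sep = "\t")
  }, character(1))
  writeLines(c("##gff-version 3", lines), path)
  path
}

# random synthetic QTL database on one or more chromosomes
random_qtl_db <- function(n, chroms = "1", seed = 1) {
  withr::with_seed(seed, {
    traits <- c("milk yield", "fat percent", "stature", "fertility",
                "mastitis resistance", "carcass weight")
    classes <- c("Milk", "Milk", "Exterior", "Reproduction", "Health",
                 "Meat_and_Carcass")
    k <- sample.int(length(traits), n, replace = TRUE,
                    prob = c(0.3, 0.2, 0.15, 0.15, 0.1, 0.1))
    start <- sample.int(5e6, n)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + sample.int(200000, n),
               kind = "QTL", name = paste0("QTL_", seq_len(n)),
               trait = traits[k], qtl_class = classes[k],
               stringsAsFactors = FALSE)
  })
}
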