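test_that("GTF gene rows parse with 1-based coordinates", {
  path <- withr::local_tempfile(fileext = ".gtf")
  write_tiny_gtf(path, data.frame(chrom = "1", start = 100, end = 200,
                                  name = "GENE1"))
  g <- parse_gtf(path)
  expect_equal(nrow(g), 1)
  expect_equal(g$start, 100)
  expect_equal(g$end, 200)
  expect_equal(g$kind, "gene")
  expect_equal(g$name, "GENE1")
})

test_that("QTL GFF rows lacking a trait are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".gff")
  write_tiny_qtl_gff(path, data.frame(
    chrom = c("1", "1"), start = c(100, 400), end = c(300, 600),
    name = c("q1", "q2"), trait = c("milk yield", NA),
    qtl_class = c("Milk", "Milk")))
  q <- parse_qtl_gff(path)
  expect_equal(nrow(q), 1)
  expect_equal(attr(q, "n_skipped"), 1)
  expect_equal(q$trait, "milk yield")
})

test_that("unknown QTL classes map to Other with a warning", {
  path <- withr::local_tempfile(fileext = ".gff")
  write_tiny_qtl_gff(path, data.frame(
    chrom = "1", start = 100, end = 300, name = "q1",
    trait = "odd trait", qtl_class = "Wool"))
  expect_warning(q <- parse_qtl_gff(path), "Other")
  expect_equal(q$qtl_class, "Other")
})

test_that("empty and ragged annotation files behave as documented", {
  path <- withr::local_tempfile(fileext = ".gff")
  writeLines("##gff-version 3", path)
  q <- parse_qtl_gff(path)
  expect_equal(nrow(q), 0)
  expect_error(parse_qtl_gff(tempfile()), "cannot read")
})

test_that("feature overlap uses closed intervals on matching chromosomes", {
  regions <- data.frame(chrom = "1", start_pos = 100L, end_pos = 200L,
                        n_snps = 2L, peak_q = 0.01, peak_pos = 150L)
  feats <- data.frame(chrom = c("1", "1", "2"),
                      start = c(150, 201, 100), end = c(300, 300, 200),
                      kind = "gene", name = c("in", "out", "offchrom"),
                      stringsAsFactors = FALSE)
  ov <- overlap_features(regions, feats)
  expect_equal(ov$name, "in")
  # inclusive end: a feature starting exactly at end_pos overlaps
  feats2 <- data.frame(chrom = "1", start = 200, end = 300, kind = "gene",
                       name = "edge", stringsAsFactors = FALSE)
  expect_equal(nrow(overlap_features(regions, feats2)), 1)
})

test_that("overlaps agree with the double-loop oracle on random instances", {
  withr::with_seed(14, {
    for (rep in 1:25) {
      nr <- sample(1:6, 1); nf <- sample(1:30, 1)
      rs <- sample.int(1000, nr)
      regions <- data.frame(chrom = sample(c("1", "2"), nr, TRUE),
                            start_pos = rs, end_pos = rs + sample.int(200, nr),
                            n_snps = 2L, peak_q = 0.01, peak_pos = rs)
      fs <- sample.int(1000, nf)
      feats <- data.frame(chrom = sample(c("1", "2"), nf, TRUE),
                          start = fs, end = fs + sample.int(200, nf),
                          kind = "gene", name = paste0("g", seq_len(nf)),
                          stringsAsFactors = FALSE)
      got <- suppressWarnings(overlap_features(regions, feats))
      want <- oracle_overlap(regions, feats)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        key_got <- sort(paste(got$region_idx, got$name))
        key_want <- sort(paste(want[, 1], feats$name[want[, 2]]))
        expect_identical(key_got, key_want)
      }
    }
  })
})

test_that("class proportions sum to 100 and handle edge cases", {
  ann <- data.frame(qtl_class = c("Milk", "Milk", "Health", "Milk"))
  p <- qtl_class_proportions(ann)
  expect_equal(sum(p$percent), 100, tolerance = 0.1)
  expect_equal(p$percent[p$qtl_class == "Milk"], 75)
  expect_equal(p$percent[p$qtl_class == "Health"], 25)
  expect_equal(qtl_class_proportions(ann[1, , drop = FALSE])$percent, 100)
  expect_equal(nrow(qtl_class_proportions(ann[0, , drop = FALSE])), 0)
})

test_that("bootstrap enrichment saturates and floors as expected", {
  db <- random_qtl_db(50, seed = 2)
  db$trait <- "milk yield"  # db contains only one trait
  ann <- db[1:5, ]
  res <- qtl_enrichment_bootstrap(ann, db, n_iter = 100, seed = 1)
  expect_equal(res$p_emp[res$trait == "milk yield"], 1)

  # observed 0 for a trait present in the db
  db2 <- random_qtl_db(50, seed = 3)
  ann2 <- db2[db2$trait == "milk yield", ][1:3, ]
  res2 <- qtl_enrichment_bootstrap(ann2, db2, n_iter = 100, seed = 1)
  other <- res2[res2$observed == 0, ]
  expect_true(all(other$p_emp == 1))

  # trait absent from the db but observed
  db3 <- random_qtl_db(50, seed = 4)
  db3$trait <- "stature"
  ann3 <- db3[1:4, ]; ann3$trait <- "novel trait"
  res3 <- qtl_enrichment_bootstrap(ann3, db3, n_iter = 100, seed = 1)
  expect_equal(res3$p_emp[res3$trait == "novel trait"], 1 / 101)

  expect_error(qtl_enrichment_bootstrap(ann3, db3, n_iter = 0), "n_iter")
  # db must cover every annotated chromosome
  ann4 <- ann3; ann4$chrom <- "99"
  expect_error(qtl_enrichment_bootstrap(ann4, db3, n_iter = 10), "99")
})

test_that("enrichment is byte-identical under a fixed seed", {
  db <- random_qtl_db(80, chroms = c("1", "2"), seed = 5)
  ann <- db[sample(1:80, 12), ]
  r1 <- qtl_enrichment_bootstrap(ann, db, n_iter = 200, seed = 99)
  r2 <- qtl_enrichment_bootstrap(ann, db, n_iter = 200, seed = 99)
  expect_identical(r1, r2)
  expect_true(all(r1$p_fdr >= r1$p_emp))
})
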