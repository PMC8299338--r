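test_that("FST is 1 for a fixed difference and 0 for identical pops", {
  n <- 10
  a <- rbind(matrix(0L, 2 * n, 5), matrix(1L, 2 * n, 5))
  hm <- hap_matrix(a, make_map(5), paste0("s", 1:(2 * n)),
                   subpop = rep(c("p1", "p2"), each = n))
  expect_equal(weir_cockerham_fst(hm), rep(1, 5))

  # identical genotype counts in both pops -> theta <= 0 -> clamped to 0
  hap <- matrix(rep(c(0L, 1L), 2 * n * 5), nrow = 4 * n)  # every sample het
  hm2 <- hap_matrix(hap, make_map(5), paste0("s", 1:(2 * n)),
                    subpop = rep(c("p1", "p2"), each = n))
  expect_equal(weir_cockerham_fst(hm2), rep(0, 5))
})

test_that("FST matches the brute-force variance-component oracle", {
  withr::with_seed(5, {
    for (rep in 1:100) {
      n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
      p1 <- runif(1, 0.1, 0.9); p2 <- runif(1, 0.1, 0.9)
      g1 <- rbinom(n1, 1, p1) + rbinom(n1, 1, p1)
      g2 <- rbinom(n2, 1, p2) + rbinom(n2, 1, p2)
      # build a hapmat whose dosages reproduce g1, g2 (phase irrelevant)
      to_h <- function(g) t(sapply(g, function(d)
        if (d == 0) c(0L, 0L) else if (d == 1) c(0L, 1L) else c(1L, 1L)))
      a <- rbind(matrix(t(to_h(g1)), ncol = 1), matrix(t(to_h(g2)), ncol = 1))
      hm <- hap_matrix(a, make_map(1), paste0("s", 1:(n1 + n2)),
                       subpop = rep(c("p1", "p2"), c(n1, n2)))
      got <- weir_cockerham_fst(hm)
      want <- oracle_wc_fst(g1, g2)
      if (is.na(want)) expect_true(is.na(got)) else
        expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("FST requires exactly two subpopulations", {
  hm <- random_hapmat(n = 6, L = 5, seed = 1)
  expect_error(weir_cockerham_fst(hm), "subpopulation")
  hm$subpop <- rep(c("a", "b", "c"), 2)
  expect_error(weir_cockerham_fst(hm), "two")
})

test_that("H1/H12 reproduce closed-form values for simple windows", {
  # all haplotypes identical
  a <- matrix(0L, 8, 14)
  hm <- hap_matrix(a, make_map(14), paste0("s", 1:4))
  hh <- haplotype_homozygosity(hm, 14, 1)
  expect_equal(hh$h1[8], 1)   # assigned at 0-based offset 7 -> index 8
  expect_equal(hh$h12[8], 1)
  expect_true(all(is.na(hh$h1[-8])))

  # two classes at 0.5 each
  a2 <- rbind(matrix(0L, 4, 14), matrix(1L, 4, 14))
  hm2 <- hap_matrix(a2, make_map(14), paste0("s", 1:4))
  hh2 <- haplotype_homozygosity(hm2, 14, 1)
  expect_equal(hh2$h1[8], 0.5)
  expect_equal(hh2$h12[8], 1.0)

  # four classes at 0.25
  base <- matrix(0L, 4, 14)
  base[2, 1] <- 1L; base[3, 2] <- 1L; base[4, 3] <- 1L
  a3 <- base[rep(1:4, each = 2), ]
  hm3 <- hap_matrix(a3, make_map(14), paste0("s", 1:4))
  hh3 <- haplotype_homozygosity(hm3, 14, 1)
  expect_equal(hh3$h1[8], 0.25)
  expect_equal(hh3$h12[8], 0.375)
})

test_that("H1/H12 match the string-pasting oracle on random inputs", {
  withr::with_seed(17, {
    for (rep in 1:100) {
      n_hap <- 2 * sample(3:10, 1)
      L <- sample(8:20, 1)
      w <- sample(3:min(8, L), 1)
      a <- matrix(rbinom(n_hap * L, 1, runif(1, 0.2, 0.8)), nrow = n_hap)
      if (rep %% 3 == 0) a[sample(length(a), 2)] <- NA
      hm <- hap_matrix(a, make_map(L), paste0("s", seq_len(n_hap / 2)))
      hh <- haplotype_homozygosity(hm, w, 1)
      for (s in seq_len(L - w + 1)) {
        target <- s + w %/% 2
        want <- oracle_h1h12(a[, s:(s + w - 1), drop = FALSE])
        expect_equal(hh$h1[target], want[["h1"]], tolerance = 1e-12)
        expect_equal(hh$h12[target], want[["h12"]], tolerance = 1e-12)
      }
      # invariant: 1/K <= H1 <= H12 <= 1
      ok <- !is.na(hh$h1)
      expect_true(all(hh$h1[ok] <= hh$h12[ok] + 1e-12))
      expect_true(all(hh$h12[ok] <= 1 + 1e-12))
    }
  })
})

test_that("short chromosomes yield missing H values with a warning", {
  hm <- random_hapmat(n = 4, L = 10, seed = 2)
  expect_warning(hh <- haplotype_homozygosity(hm, 14, 1), "fewer than")
  expect_true(all(is.na(hh$h1)))
})

test_that("Tajima's D matches the direct-formula oracle", {
  # the 4-haplotype ladder
  a <- rbind(c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 1L, 1L), c(1L, 1L, 1L))
  hm <- hap_matrix(a, make_map(3), c("s1", "s2"))
  expect_equal(tajimas_d(hm, 1e9), rep(oracle_tajima_d(a), 3),
               tolerance = 1e-12)

  withr::with_seed(23, {
    for (rep in 1:100) {
      n_hap <- 10; L <- 20
      a <- matrix(rbinom(n_hap * L, 1, runif(L, 0.05, 0.95)), nrow = n_hap,
                  byrow = FALSE)
      hm <- hap_matrix(a, make_map(L), paste0("s", 1:5))
      expect_equal(tajimas_d(hm, 1e9), rep(oracle_tajima_d(a), L),
                   tolerance = 1e-12)
    }
  })
})

test_that("bins without segregating sites give D = 0 and n < 4 errors", {
  a <- matrix(0L, 6, 4)
  hm <- hap_matrix(a, make_map(4), paste0("s", 1:3))
  expect_equal(tajimas_d(hm), rep(0, 4))
  hm2 <- hap_matrix(matrix(c(0L, 1L), 2, 3), make_map(3), "s1")
  expect_error(tajimas_d(hm2), "4 haplotypes")
})

test_that("per-site pi follows the closed form and the pair-counting oracle", {
  a <- matrix(c(0L, 0L, 1L, 1L,   # j=2, n=4 -> 2/3
                0L, 0L, 0L, 0L,   # monomorphic -> 0
                1L, 1L, 1L, 1L), nrow = 4)
  hm <- hap_matrix(a, make_map(3), c("s1", "s2"))
  expect_equal(site_pi(hm), c(2 / 3, 0, 0))

  withr::with_seed(31, {
    a2 <- matrix(rbinom(10 * 30, 1, 0.3), nrow = 10)
    a2[sample(length(a2), 10)] <- NA
    hm2 <- hap_matrix(a2, make_map(30), paste0("s", 1:5))
    got <- site_pi(hm2)
    want <- apply(a2, 2, oracle_site_pi)
    expect_equal(got, want, tolerance = 1e-12)
  })
  # n=10, j=3 closed form
  a3 <- matrix(c(rep(1L, 3), rep(0L, 7)), nrow = 10, ncol = 1)
  hm3 <- hap_matrix(a3, make_map(1), paste0("s", 1:5))
  expect_equal(site_pi(hm3), 7 / 15)
})

test_that("running median smooths with the constant end rule", {
  expect_equal(running_median(c(1, 9, 2, 8, 3), smooth_k = 3),
               c(2, 2, 8, 3, 3))
  v <- rep(2, 40)
  expect_equal(running_median(v, smooth_k = 31), v)
  v2 <- rep(0, 41); v2[20] <- 1
  expect_equal(running_median(v2, smooth_k = 31), rep(0, 41))
  # missing imputed to zero before smoothing
  v3 <- c(NA, NA, NA, 5, NA)
  expect_equal(running_median(v3, smooth_k = 3), c(0, 0, 0, 0, 0))
  # chromosomes smoothed independently
  v4 <- c(1, 1, 1, 9, 9, 9)
  chr <- rep(c("1", "2"), each = 3)
  expect_equal(running_median(v4, chr, 3), v4)
})

test_that("median smoothing commutes with monotone transformations", {
  withr::with_seed(7, {
    v <- rnorm(100)
    chr <- rep("1", 100)
    f <- function(x) x^3 + 2 * x   # strictly increasing
    expect_equal(running_median(f(v), chr, 9), f(running_median(v, chr, 9)))
  })
})
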