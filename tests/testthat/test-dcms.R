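test_that("fractional-rank p-values follow the rank formulas and bounds", {
  expect_equal(fractional_rank_pvalues(c(1, 2, 3), "right"),
               c(3, 2, 1) / 4)
  expect_equal(fractional_rank_pvalues(c(1, 2, 3), "left"),
               c(1, 2, 3) / 4)
  p <- fractional_rank_pvalues(c(5, 5), "right")
  expect_equal(p[1], p[2])  # ties share the average rank
  # extremes hit the fractional-rank bounds exactly
  withr::with_seed(2, {
    v <- rnorm(101)
    pl <- fractional_rank_pvalues(v, "left")
    expect_equal(min(pl), 1 / 102)
    expect_equal(max(pl), 101 / 102)
  })
  expect_error(fractional_rank_pvalues(numeric(0), "left"), "empty")
})

test_that("fractional ranks match the tie-averaging oracle on random input", {
  withr::with_seed(13, {
    for (rep in 1:50) {
      v <- sample(rnorm(15), 20, replace = TRUE)  # guaranteed ties
      for (tail in c("left", "right", "two")) {
        expect_equal(fractional_rank_pvalues(v, tail), oracle_frac_p(v, tail),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("MCD correlation recovers known structure", {
  withr::with_seed(3, {
    n <- 5000
    z <- rnorm(n)
    X <- cbind(a = z, b = 0.8 * z + sqrt(1 - 0.64) * rnorm(n),
               c = rnorm(n), d = rnorm(n), e = rnorm(n))
    R <- robust_correlation_mcd(X, nsamp = 500, seed = 42)
    expect_equal(R["a", "b"], 0.8, tolerance = 0.05)
    expect_lt(max(abs(R[c("a", "b"), c("c", "d", "e")])), 0.05)
    expect_equal(unname(diag(R)), rep(1, 5))
    expect_equal(R, t(R))
    expect_gte(min(eigen(R, symmetric = TRUE)$values), -1e-8)
    # identical columns correlate at 1
    X2 <- cbind(z, z, rnorm(n))
    R2 <- suppressWarnings(robust_correlation_mcd(X2, nsamp = 200, seed = 1))
    expect_equal(R2[1, 2], 1, tolerance = 1e-8)
  })
})

test_that("MCD is reproducible under a fixed seed", {
  withr::with_seed(9, X <- matrix(rnorm(500 * 5), ncol = 5))
  R1 <- robust_correlation_mcd(X, nsamp = 300, seed = 7)
  R2 <- robust_correlation_mcd(X, nsamp = 300, seed = 7)
  expect_identical(R1, R2)
})

test_that("DCMS algebra: zero at p=0.5, single logit, no double counting", {
  P <- matrix(0.5, nrow = 3, ncol = 5)
  I5 <- diag(5)
  expect_equal(dcms_combine(P, I5), rep(0, 3))

  P2 <- matrix(c(0.1, 0.5, 0.5, 0.5, 0.5), nrow = 1)
  expect_equal(dcms_combine(P2, I5), log(9), tolerance = 1e-12)

  # perfectly correlated statistics: w_t = 1/5, identical p -> single logit
  ones <- matrix(1, 5, 5)
  P3 <- matrix(0.2, nrow = 4, ncol = 5)
  expect_equal(dcms_combine(P3, ones), rep(log(0.8 / 0.2), 4),
               tolerance = 1e-12)

  # identity correlation equals the unweighted sum of logits
  withr::with_seed(21, P4 <- matrix(runif(50, 0.01, 0.99), ncol = 5))
  expect_equal(dcms_combine(P4, I5), rowSums(log((1 - P4) / P4)),
               tolerance = 1e-12)

  expect_error(dcms_combine(matrix(c(0, 0.5), 1), diag(2)), "strictly")
})

test_that("DCMS decreases strictly in each p-value", {
  withr::with_seed(4, {
    R <- stats::cov2cor(crossprod(matrix(rnorm(100), 20, 5)))
    p0 <- runif(5, 0.2, 0.8)
    base <- dcms_combine(matrix(p0, 1), R)
    for (t in 1:5) {
      p_up <- p0; p_up[t] <- p0[t] + 0.1
      expect_lt(dcms_combine(matrix(p_up, 1), R), base)
    }
  })
})

test_that("Huber location is resistant where the mean is not", {
  withr::with_seed(6, {
    x <- rnorm(1e5)
    fit <- robust_normal_fit(x)
    expect_equal(fit$mu, 0, tolerance = 0.02)
    expect_equal(fit$sigma, 1, tolerance = 0.02)

    x_cont <- x
    idx <- sample(length(x), length(x) * 0.05)
    x_cont[idx] <- 100
    fit_c <- robust_normal_fit(x_cont)
    expect_lt(abs(fit_c$mu), 0.1)
    expect_gt(abs(mean(x_cont)), 4.5)  # the plain mean is dragged to ~5

    # agreement with the rlm-style M-estimator on clean data (absolute scale:
    # both locations sit at ~0, so relative tolerance is meaningless)
    rl <- MASS::rlm(x ~ 1, k = 1.345)
    expect_lt(abs(fit$mu - unname(coef(rl)[1])), 1e-4)
  })
})

test_that("robust fit degenerates loudly", {
  expect_error(robust_normal_fit(rep(1, 100)), "spread")
  expect_error(robust_normal_fit(rnorm(10)), "at least 30")
  # symmetric data: location equals the median
  x <- c(-(50:1), 0, 1:50) / 10
  expect_equal(robust_normal_fit(x)$mu, stats::median(x), tolerance = 1e-6)
})

test_that("upper-tail p-values follow the normal CDF", {
  expect_equal(upper_tail_p(3, 3, 2), 0.5)
  expect_equal(upper_tail_p(1.959964, 0, 1), 0.025, tolerance = 1e-6)
  p <- upper_tail_p(c(1, 2, 3), 0, 1)
  expect_true(all(diff(p) < 0))
  expect_error(upper_tail_p(1, 0, 0), "positive")
})

test_that("BH q-values match the step-up oracle exactly", {
  expect_equal(bh_qvalues(0.03), 0.03)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_qvalues(c(0.04, 1.0)), c(0.08, 1.0))
  withr::with_seed(8, {
    for (rep in 1:1000) {
      p <- runif(sample(1:20, 1))
      expect_equal(bh_qvalues(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
})
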