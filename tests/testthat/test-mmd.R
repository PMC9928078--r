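test_that("Gaussian kernel has unit diagonal and closed-form values", {
  x <- matrix(c(0, 1), ncol = 1)
  K <- gaussian_kernel_matrix(x, sigma = 1)
  expect_equal(diag(K), c(1, 1))
  expect_equal(K[1L, 2L], exp(-0.5))
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  expect_error(gaussian_kernel_matrix(x, sigma = 0), "positive")
})

test_that("median bandwidth enumerates pooled pairwise distances", {
  expect_equal(median_bandwidth(matrix(c(0, 1, 3), ncol = 1)), 2)
  ## duplicated points: distances {0, d, d} -> median d
  expect_equal(median_bandwidth(matrix(c(0, 0, 5), ncol = 1)), 5)
  ## homogeneity of degree 1
  set.seed(1)
  pts <- matrix(rnorm(40), ncol = 2)
  expect_equal(median_bandwidth(pts * 3), 3 * median_bandwidth(pts))
  expect_error(median_bandwidth(matrix(1, 4, 2)), "identical")
})

test_that("unbiased MMD^2 matches closed forms and the brute-force oracle", {
  a <- matrix(c(0.3, 0.3), ncol = 1)
  expect_equal(mmd_u_squared(a, a, sigma = 1), 0)
  x01 <- matrix(c(0, 1), ncol = 1)
  expect_equal(mmd_u_squared(x01, x01, sigma = 1), exp(-0.5) - 1)
  set.seed(2)
  for (r in 1:100) {
    m <- sample(2:6, 1); n <- sample(2:6, 1); d <- sample(1:3, 1)
    X <- matrix(rnorm(m * d), m); Y <- matrix(rnorm(n * d), n)
    s <- runif(1, 0.3, 3)
    expect_equal(mmd_u_squared(X, Y, s), mmd_u2_bruteforce(X, Y, s),
                 tolerance = 1e-12)
    ## symmetry in X <-> Y
    expect_equal(mmd_u_squared(X, Y, s), mmd_u_squared(Y, X, s),
                 tolerance = 1e-12)
  }
  expect_error(mmd_u_squared(matrix(0), matrix(c(1, 2))), "at least 2")
})

test_that("MMD_u^2 is unbiased: zero mean under the null", {
  set.seed(3)
  vals <- replicate(1000, {
    mmd_u_squared(matrix(rnorm(20), ncol = 2), matrix(rnorm(20), ncol = 2),
                  sigma = 1)
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
  expect_true(any(vals < 0))   # the unbiased estimator goes negative
})

test_that("size equalization subsamples the larger set only", {
  set.seed(4)
  X <- matrix(rnorm(600), ncol = 2); Y <- matrix(rnorm(200), ncol = 2)
  eq <- equalize_sizes(X, Y, seed = 5)
  expect_equal(nrow(eq$X), 100L)
  expect_equal(eq$Y, Y)
  expect_true(all(eq$X %in% X))
  expect_identical(equalize_sizes(X, Y, seed = 5), eq)
  same <- equalize_sizes(Y, Y, seed = 5)
  expect_identical(same$X, Y); expect_identical(same$Y, Y)
})

test_that("length marginalization equalises per-length histograms", {
  X <- matrix(rnorm(20), ncol = 2); Y <- matrix(rnorm(18), ncol = 2)
  len_x <- c(rep(7L, 10)); len_y <- c(rep(7L, 4), rep(8L, 5))
  mm <- marginalize_by_length(X[1:10, ], Y[1:9, ], len_x, len_y, seed = 1)
  expect_equal(nrow(mm$X), 4L)
  expect_equal(nrow(mm$Y), 4L)
  ## per-length counts equal for every length
  set.seed(6)
  lx <- sample(7:12, 40, replace = TRUE); ly <- sample(9:15, 50, replace = TRUE)
  mm2 <- marginalize_by_length(matrix(rnorm(80), ncol = 2),
                               matrix(rnorm(100), ncol = 2), lx, ly, seed = 2)
  expect_equal(table(lx[mm2$ix]), table(ly[mm2$iy]))
  expect_error(marginalize_by_length(X[1:2, ], Y[1:2, ], c(7, 7), c(9, 9)),
               "no comparable")
})

test_that("permutation test calibrates under H0 and detects separation", {
  ## same distribution: identical multiset is never an extreme value
  set.seed(7)
  Z <- matrix(rnorm(60), ncol = 2)
  r0 <- mmd_test(Z, Z, B = 200, seed = 1)
  expect_false(r0$reject)
  expect_gt(r0$p_value, 0.5)
  ## two Gaussians 10 sigma apart: p at its minimum, rejected
  X <- matrix(rnorm(200), ncol = 2)
  Y <- matrix(rnorm(200), ncol = 2) + 10
  r1 <- mmd_test(X, Y, B = 300, seed = 2)
  expect_true(r1$reject)
  expect_equal(r1$p_value, 1 / 301)
  ## reproducibility by seed
  r2 <- mmd_test(X, Y, B = 300, seed = 2)
  expect_identical(r1$mmd_u2, r2$mmd_u2)
  expect_identical(r1$null_samples, r2$null_samples)
})

test_that("permutation p-values are super-uniform under H0", {
  set.seed(8)
  ps <- replicate(200, {
    mmd_test(matrix(rnorm(40), ncol = 2), matrix(rnorm(40), ncol = 2),
             B = 100)$p_value
  })
  expect_lte(mean(ps <= 0.05), 0.08)
})

test_that("the vectorized permutation null matches direct recomputation", {
  set.seed(9)
  X <- matrix(rnorm(16), ncol = 2); Y <- matrix(rnorm(12), ncol = 2)
  sig <- median_bandwidth(rbind(X, Y))
  K <- gaussian_kernel_matrix(rbind(X, Y), sigma = sig)
  m <- nrow(X); n <- nrow(Y)
  set.seed(10)
  null_fast <- walkmmd:::mmd_perm_null(K, m, n, 25L)
  set.seed(10)
  pooled <- rbind(X, Y)
  null_slow <- replicate(25, {
    idx <- sample.int(m + n, m)
    mmd_u_squared(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE], sig)
  })
  expect_equal(null_fast, null_slow, tolerance = 1e-10)
})

test_that("Hotelling baseline reduces to the t-test in 1D", {
  set.seed(11)
  x <- rnorm(30); y <- rnorm(25, mean = 0.5)
  h <- hotelling_test(matrix(x), matrix(y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(h$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(h$p_value, tt$p.value, tolerance = 1e-10)
  ## identical sets: T^2 = 0, p = 1
  X <- matrix(rnorm(40), ncol = 2)
  h0 <- hotelling_test(X, X)
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p_value, 1)
})

test_that("MMD out-powers Hotelling on equal-mean shape differences", {
  ## two 2D distributions with identical means but different shapes
  set.seed(12)
  n_rep <- 30
  rej <- matrix(FALSE, n_rep, 2)
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(200), ncol = 2)                       # round cloud
    th <- runif(100, 0, 2 * pi)
    Y <- cbind(2.2 * cos(th), 2.2 * sin(th)) +
      matrix(rnorm(200, sd = 0.3), ncol = 2)                # ring, same mean
    rej[r, 1L] <- mmd_test(X, Y, B = 100, seed = r)$reject
    rej[r, 2L] <- hotelling_test(X, Y)$p_value < 0.05
  }
  expect_gt(mean(rej[, 1L]), mean(rej[, 2L]))
})
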