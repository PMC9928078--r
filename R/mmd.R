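#' Gaussian kernel matrix
#'
#' Entries exp(-||a - b||^2 / (2 sigma^2)). The unit-amplitude form is used
#' throughout: a constant kernel prefactor scales every MMD estimate
#' uniformly and cancels in the permutation test.
#'
#' @param A,B numeric matrices (rows are points of a common dimension).
#' @param sigma kernel bandwidth (> 0).
#' @return |A| x |B| matrix with values in (0, 1].
#' @export
gaussian_kernel_matrix <- function(A, B = A, sigma) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("point sets must share dimension")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Median-heuristic kernel bandwidth
#'
#' The median of all pairwise Euclidean distances of the pooled sample, the
#' standard bandwidth heuristic for the Gaussian kernel.
#'
#' @param points pooled numeric matrix (rows are points).
#' @return positive bandwidth.
#' @export
median_bandwidth <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  m <- stats::median(stats::dist(points))
  if (!is.finite(m) || m <= 0)
    stop("all points identical: supply an explicit bandwidth")
  m
}

#' Unbiased squared maximum mean discrepancy
#'
#' The U-statistic estimator of MMD^2 between samples X and Y:
#' the two within-sample kernel means exclude the diagonal, so the estimate
#' is unbiased and may be negative.
#'
#' @param X,Y numeric matrices (m and n rows, m, n >= 2).
#' @param sigma Gaussian kernel bandwidth, or `"median"` to use
#'   [median_bandwidth()] of the pooled sample.
#' @return scalar MMD_u^2.
#' @export
mmd_u_squared <- function(X, Y, sigma = "median") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X); n <- nrow(Y)
  if (m < 2L || n < 2L) stop("both samples need at least 2 points")
  if (identical(sigma, "median")) sigma <- median_bandwidth(rbind(X, Y))
  Kxx <- gaussian_kernel_matrix(X, X, sigma)
  Kyy <- gaussian_kernel_matrix(Y, Y, sigma)
  Kxy <- gaussian_kernel_matrix(X, Y, sigma)
  (sum(Kxx) - sum(diag(Kxx))) / (m * (m - 1)) +
    (sum(Kyy) - sum(diag(Kyy))) / (n * (n - 1)) -
    2 * sum(Kxy) / (m * n)
}

#' Equalize two sample sizes by subsampling
#'
#' Randomly subsamples (without replacement) the larger of the two sets to
#' the size of the smaller, so that both replicates weigh equally in the
#' comparison.
#'
#' @param X,Y numeric matrices.
#' @param seed optional RNG seed.
#' @return list with equal-sized `X` and `Y`.
#' @export
equalize_sizes <- function(X, Y, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!nrow(X) || !nrow(Y)) stop("both sets must be non-empty")
  with_seed(seed, {
    if (nrow(X) > nrow(Y)) {
      X <- X[sample.int(nrow(X), nrow(Y)), , drop = FALSE]
    } else if (nrow(Y) > nrow(X)) {
      Y <- Y[sample.int(nrow(Y), nrow(X)), , drop = FALSE]
    }
    list(X = X, Y = Y)
  })
}

#' Marginalize two feature sets by trajectory length
#'
#' Trajectory length influences the descriptive vectors irrespective of the
#' underlying dynamics; to compare dynamics only, both sets are subsampled
#' so that their per-length histograms coincide (per integer length, each
#' set keeps the minimum of the two counts, chosen at random).
#'
#' @param X,Y numeric feature matrices.
#' @param len_x,len_y integer trajectory lengths, one per row of X / Y.
#' @param seed optional RNG seed.
#' @return list with matched `X`, `Y` and the kept row indices `ix`, `iy`.
#' @export
marginalize_by_length <- function(X, Y, len_x, len_y, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(length(len_x) == nrow(X), length(len_y) == nrow(Y))
  lens <- intersect(unique(len_x), unique(len_y))
  if (!length(lens)) stop("no comparable trajectories: length supports disjoint")
  with_seed(seed, {
    ix <- integer(0); iy <- integer(0)
    for (L in lens) {
      wx <- which(len_x == L); wy <- which(len_y == L)
      keep <- min(length(wx), length(wy))
      ix <- c(ix, if (length(wx) > keep) sample(wx, keep) else wx)
      iy <- c(iy, if (length(wy) > keep) sample(wy, keep) else wy)
    }
    list(X = X[ix, , drop = FALSE], Y = Y[iy, , drop = FALSE], ix = ix, iy = iy)
  })
}

## Vectorized permutation null of MMD_u^2 from the pooled kernel matrix.
## For each permutation, membership indicators a (X') and b (Y') give
## S_xx = a'Ka, S_yy = b'Kb, S_xy = a'Kb (diagonals included), from which
## the unbiased statistic follows. Returns B null values.
mmd_perm_null <- function(K, m, n, B) {
  N <- m + n
  A <- matrix(0, N, B)
  for (b in seq_len(B)) A[sample.int(N, m), b] <- 1
  Bm <- 1 - A
  KA <- K %*% A
  Sxx <- colSums(A * KA)
  Sxy <- colSums(Bm * KA)
  Syy <- colSums(Bm * (K %*% Bm))
  dK <- diag(K)
  dxx <- colSums(A * dK)    # sum of diagonal entries within X'
  dyy <- colSums(Bm * dK)
  (Sxx - dxx) / (m * (m - 1)) + (Syy - dyy) / (n * (n - 1)) - 2 * Sxy / (m * n)
}

#' Kernel two-sample MMD permutation test
#'
#' Tests whether two sets of descriptive vectors are drawn from the same
#' distribution, using the unbiased squared MMD with a Gaussian kernel and a
#' permutation (bootstrap) null: the pooled sample is repeatedly
#' re-partitioned at random into two groups of the original sizes and the
#' statistic recomputed. The null hypothesis is rejected at level `beta`
#' when the observed statistic exceeds the empirical (1 - beta) quantile of
#' the null sample. The bandwidth is resolved once on the pooled observed
#' sample and reused for all permutations.
#'
#' @param X,Y numeric feature matrices (rows are per-trajectory vectors).
#' @param sigma Gaussian kernel bandwidth, or `"median"` (default).
#' @param B number of permutations (default 1000).
#' @param beta test level (default 0.05).
#' @param equalize subsample the larger set to equalise sizes (default TRUE).
#' @param len_x,len_y optional trajectory lengths; when both are given the
#'   comparison is first marginalized by length
#'   ([marginalize_by_length()]).
#' @param seed optional RNG seed.
#' @return object of class `"mmd_test"`: list with `mmd_u2`, `null_samples`,
#'   `p_value` (with the +1 correction, so always > 0), `reject`, `beta`,
#'   `m`, `n`, `sigma`, `B`.
#' @export
mmd_test <- function(X, Y, sigma = "median", B = 1000L, beta = 0.05,
                     equalize = TRUE, len_x = NULL, len_y = NULL,
                     seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (B < 1L) stop("B must be >= 1")
  seeds <- derive_seeds(seed, 3L)
  if (!is.null(len_x) && !is.null(len_y)) {
    mm <- marginalize_by_length(X, Y, len_x, len_y, seed = seeds[1L])
    X <- mm$X; Y <- mm$Y
  }
  if (equalize) {
    eq <- equalize_sizes(X, Y, seed = seeds[2L])
    X <- eq$X; Y <- eq$Y
  }
  m <- nrow(X); n <- nrow(Y)
  if (m < 2L || n < 2L) stop("need at least 2 points per set after matching")
  if (identical(sigma, "median")) sigma <- median_bandwidth(rbind(X, Y))
  K <- gaussian_kernel_matrix(rbind(X, Y), sigma = sigma)
  dxx <- sum(diag(K)[seq_len(m)]); dyy <- sum(diag(K)) - dxx
  obs <- (sum(K[seq_len(m), seq_len(m)]) - dxx) / (m * (m - 1)) +
    (sum(K[m + seq_len(n), m + seq_len(n)]) - dyy) / (n * (n - 1)) -
    2 * sum(K[seq_len(m), m + seq_len(n)]) / (m * n)
  null <- with_seed(seeds[3L], mmd_perm_null(K, m, n, as.integer(B)))
  p <- (1 + sum(null >= obs)) / (B + 1)
  crit <- stats::quantile(null, 1 - beta, names = FALSE, type = 1)
  structure(
    list(mmd_u2 = obs, null_samples = null, p_value = p,
         reject = obs > crit, beta = beta, m = m, n = n, sigma = sigma,
         B = as.integer(B), seed = seed),
    class = "mmd_test"
  )
}

#' @export
print.mmd_test <- function(x, ...) {
  cat("Kernel two-sample MMD permutation test\n")
  cat(sprintf("  MMD_u^2 = %.4g   (m = %d, n = %d, sigma = %.4g, B = %d)\n",
              x$mmd_u2, x$m, x$n, x$sigma, x$B))
  cat(sprintf("  p = %.4g  -> %s H0 at level %.3g\n", x$p_value,
              if (x$reject) "reject" else "do not reject", x$beta))
  invisible(x)
}

#' @export
plot.mmd_test <- function(x, ...) {
  graphics::hist(x$null_samples, breaks = 40, main = "MMD_u^2 null distribution",
                 xlab = expression(MMD[u]^2),
                 xlim = range(c(x$null_samples, x$mmd_u2)), ...)
  graphics::abline(v = stats::quantile(x$null_samples, 1 - x$beta), col = "darkgreen", lwd = 2)
  graphics::abline(v = x$mmd_u2, col = "red", lwd = 2)
  invisible(x)
}

#' Two-sample Hotelling T-squared baseline
#'
#' Classical multivariate mean-difference test with pooled covariance; in one
#' dimension the statistic equals the squared two-sample t statistic. Serves
#' as the parametric baseline against the MMD test, which is also sensitive
#' to differences beyond the mean.
#'
#' @param X,Y numeric matrices with common dimension d < m + n - 2.
#' @return list with `statistic` (T^2), `f_statistic`, `df`, `p_value`.
#' @export
hotelling_test <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X); n <- nrow(Y); d <- ncol(X)
  if (ncol(Y) != d) stop("dimension mismatch")
  if (d >= m + n - 1) stop("dimension too large for the sample sizes")
  S <- ((m - 1) * stats::cov(X) + (n - 1) * stats::cov(Y)) / (m + n - 2)
  dm <- colMeans(X) - colMeans(Y)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular pooled covariance; consider regularizing the features"))
  t2 <- (m * n / (m + n)) * drop(t(dm) %*% Sinv %*% dm)
  f <- (m + n - d - 1) / (d * (m + n - 2)) * t2
  p <- stats::pf(f, d, m + n - d - 1, lower.tail = FALSE)
  list(statistic = t2, f_statistic = f, df = c(d, m + n - d - 1), p_value = p)
}
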