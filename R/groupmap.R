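#' Pairwise MMD distance matrix between trajectory groups
#'
#' Computes the unbiased squared MMD between the feature sets of every pair
#' of groups (e.g. synapses), after size equalisation, together with a
#' per-entry variance estimate used downstream to weight the embedding.
#' Groups with fewer than `min_trajectories` feature vectors are dropped
#' (small groups make the MMD estimate too noisy; a few hundred
#' trajectories per group is usually sufficient).
#'
#' @param features named list of numeric feature matrices, one per group.
#' @param sigma Gaussian kernel bandwidth, or `"median"` (resolved once on
#'   the pooled sample of all groups).
#' @param min_trajectories minimal group size (default 150).
#' @param n_subsamples subsamples for the variance estimate
#'   ([estimate_mmd_variance()]).
#' @param seed optional RNG seed.
#' @return object of class `"group_mmd"`: list with `ids`, `d2` (squared
#'   distance matrix), `var` (variance matrix), `counts`, `sigma`,
#'   `min_trajectories`.
#' @export
pairwise_group_mmd <- function(features, sigma = "median",
                               min_trajectories = 150L, n_subsamples = 50L,
                               seed = NULL) {
  stopifnot(is.list(features), !is.null(names(features)))
  counts <- vapply(features, nrow, integer(1))
  keep <- counts >= min_trajectories
  if (sum(keep) < 2L)
    stop(sprintf("fewer than 2 groups have >= %d trajectories", min_trajectories))
  features <- features[keep]
  ids <- names(features)
  g <- length(features)
  if (identical(sigma, "median"))
    sigma <- median_bandwidth(do.call(rbind, features))
  d2 <- matrix(0, g, g, dimnames = list(ids, ids))
  v <- matrix(0, g, g, dimnames = list(ids, ids))
  seeds <- derive_seeds(seed, g * g)
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    sij <- seeds[(i - 1L) * g + j]
    eq <- equalize_sizes(features[[i]], features[[j]], seed = sij)
    d2[i, j] <- d2[j, i] <- mmd_u_squared(eq$X, eq$Y, sigma)
    v[i, j] <- v[j, i] <- estimate_mmd_variance(eq$X, eq$Y, sigma,
                                                n_subsamples = n_subsamples,
                                                seed = sij + 1L)
  }
  structure(list(ids = ids, d2 = d2, var = v, counts = counts[keep],
                 sigma = sigma, min_trajectories = min_trajectories),
            class = "group_mmd")
}

#' @export
print.group_mmd <- function(x, ...) {
  cat(sprintf("<group_mmd> %d groups (>= %d trajectories each), sigma = %.4g\n",
              length(x$ids), x$min_trajectories, x$sigma))
  invisible(x)
}

#' Variance of the unbiased squared MMD estimate
#'
#' Estimates the sampling variance of MMD_u^2 by recomputing it on repeated
#' half-subsamples of both sets and rescaling the observed spread to full
#' size using the 1/n convergence rate of the U-statistic variance (under
#' the alternative the dominant variance term of MMD_u^2 is O(1/n); halving
#' n doubles it).
#'
#' @param X,Y numeric matrices with at least 4 rows each.
#' @param sigma kernel bandwidth, or `"median"`.
#' @param n_subsamples number of half-subsample replicates (default 50).
#' @param seed optional RNG seed.
#' @return positive variance estimate for the full-size statistic.
#' @export
estimate_mmd_variance <- function(X, Y, sigma = "median", n_subsamples = 50L,
                                  seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X); n <- nrow(Y)
  if (m < 4L || n < 4L) stop("variance estimation needs at least 4 points per set")
  if (identical(sigma, "median")) sigma <- median_bandwidth(rbind(X, Y))
  hm <- m %/% 2L; hn <- n %/% 2L
  vals <- with_seed(seed, vapply(seq_len(n_subsamples), function(b) {
    mmd_u_squared(X[sample.int(m, hm), , drop = FALSE],
                  Y[sample.int(n, hn), , drop = FALSE], sigma)
  }, numeric(1)))
  v_half <- stats::var(vals)
  ## half-size variance ~ 2x the full-size one under the 1/n rate
  max(v_half / 2, .Machine$double.xmin)
}

#' Uncertainty-weighted multidimensional scaling
#'
#' Embeds groups in a low-dimensional Euclidean space from their pairwise
#' squared MMD matrix, minimising a weighted stress
#' sum_{i<j} w_ij (d_ij(Z) - delta_ij)^2 with weights proportional to the
#' inverse variance of each distance estimate, by SMACOF majorization.
#' Negative (unbiased) squared distances are clamped to zero before taking
#' the square root; entries known with high uncertainty thus barely
#' constrain the configuration. Several random restarts are run and the
#' best final stress kept.
#'
#' @param gd a `"group_mmd"` object, or a list with `d2` and `var` matrices.
#' @param embed_dim embedding dimension (default 3).
#' @param n_restarts random restarts (default 4).
#' @param max_iter majorization iterations per restart.
#' @param tol relative stress-improvement stopping tolerance.
#' @param seed optional RNG seed.
#' @return object of class `"group_embedding"`: list with `coords`
#'   (groups x embed_dim), `stress`, `ids`, `seed`.
#' @export
mds_with_uncertainty <- function(gd, embed_dim = 3L, n_restarts = 4L,
                                 max_iter = 300L, tol = 1e-10, seed = NULL) {
  d2 <- gd$d2; v <- gd$var
  g <- nrow(d2)
  if (embed_dim < 1L) stop("embed_dim must be >= 1")
  delta <- sqrt(pmax(d2, 0))
  w <- 1 / v; diag(w) <- 0
  if (any(!is.finite(w[upper.tri(w)]))) stop("non-finite weights: check variances")
  w <- w / mean(w[upper.tri(w)])
  stress_of <- function(Z) {
    dz <- as.matrix(stats::dist(Z))
    sum(w[upper.tri(w)] * (dz[upper.tri(dz)] - delta[upper.tri(delta)])^2)
  }
  V <- -w; diag(V) <- rowSums(w)
  Vp <- MASS::ginv(V)
  best <- NULL
  seeds <- derive_seeds(seed, n_restarts)
  for (r in seq_len(n_restarts)) {
    Z <- with_seed(seeds[r], matrix(stats::rnorm(g * embed_dim), g) *
                     (max(delta) / 2 + 1e-12))
    s_prev <- stress_of(Z)
    for (it in seq_len(max_iter)) {
      dz <- as.matrix(stats::dist(Z))
      ratio <- ifelse(dz > 0, delta / dz, 0)
      Bm <- -w * ratio
      diag(Bm) <- 0; diag(Bm) <- -rowSums(Bm)
      Z <- Vp %*% (Bm %*% Z)
      s_new <- stress_of(Z)
      if (s_prev - s_new < tol * max(s_prev, 1e-300)) { s_prev <- s_new; break }
      s_prev <- s_new
    }
    if (is.null(best) || s_prev < best$stress)
      best <- list(coords = Z, stress = s_prev)
  }
  rownames(best$coords) <- gd$ids %||% rownames(d2)
  structure(list(coords = best$coords, stress = best$stress,
                 ids = rownames(best$coords), seed = seed),
            class = "group_embedding")
}

#' @export
print.group_embedding <- function(x, ...) {
  cat(sprintf("<group_embedding> %d groups in %d dimensions, stress = %.4g\n",
              nrow(x$coords), ncol(x$coords), x$stress))
  invisible(x)
}
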