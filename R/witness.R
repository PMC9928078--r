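## Build a regular grid spanning the pooled data range plus a margin.
latent_grid <- function(points, n_grid = 100L, margin = 0.1) {
  rx <- range(points[, 1L]); ry <- range(points[, 2L])
  ex <- diff(rx) * margin; ey <- diff(ry) * margin
  list(x = seq(rx[1L] - ex, rx[2L] + ex, length.out = n_grid),
       y = seq(ry[1L] - ey, ry[2L] + ey, length.out = n_grid))
}

#' Empirical witness function on a grid
#'
#' The witness function of the MMD is the difference of the kernel mean
#' embeddings of the two samples, f(z) = mean_i k(x_i, z) - mean_j k(y_j, z):
#' positive where X over-occupies the latent plane, negative where Y does.
#' Swapping the samples negates the field.
#'
#' @param X,Y numeric matrices of 2D points.
#' @param sigma Gaussian kernel bandwidth, or `"median"`.
#' @param grid list with numeric vectors `x` and `y` (grid axes); defaults
#'   to a 100 x 100 lattice over the pooled range plus a 10% margin.
#' @return object of class `"witness_field"`: list with `x`, `y`, `witness`
#'   (|x| x |y| matrix), `sigma`.
#' @export
witness_function <- function(X, Y, sigma = "median", grid = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != 2L || ncol(Y) != 2L) stop("witness fields are 2D")
  if (identical(sigma, "median")) sigma <- median_bandwidth(rbind(X, Y))
  if (is.null(grid)) grid <- latent_grid(rbind(X, Y))
  if (!length(grid$x) || !length(grid$y)) stop("empty grid")
  G <- as.matrix(expand.grid(x = grid$x, y = grid$y))
  f <- colMeans(gaussian_kernel_matrix(X, G, sigma)) -
       colMeans(gaussian_kernel_matrix(Y, G, sigma))
  structure(list(x = grid$x, y = grid$y,
                 witness = matrix(f, length(grid$x), length(grid$y)),
                 sigma = sigma),
            class = "witness_field")
}

#' @export
print.witness_field <- function(x, ...) {
  cat(sprintf("<witness_field> %d x %d grid, sigma = %.4g, range [%.3g, %.3g]\n",
              length(x$x), length(x$y), x$sigma, min(x$witness), max(x$witness)))
  if (!is.null(x$s)) cat(sprintf("  S statistic: max %.3g\n", max(x$s)))
  invisible(x)
}

#' @export
plot.witness_field <- function(x, which = c("witness", "s"), ...) {
  which <- match.arg(which)
  z <- if (which == "s" && !is.null(x$s)) x$s else x$witness
  graphics::image(x$x, x$y, z, xlab = "latent 1", ylab = "latent 2",
                  main = if (which == "s") "S statistic" else "witness function",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  graphics::contour(x$x, x$y, z, add = TRUE, drawlabels = FALSE)
  invisible(x)
}

#' S statistic of the witness function
#'
#' Per grid point, the ratio of the squared mean amplitude of the witness
#' function to its variance, both estimated by bootstrapping (resampling
#' with replacement within each sample). Large S marks latent regions whose
#' occupancy differs most reliably between the two conditions. The variance
#' is floored at a small epsilon relative to the maximal squared witness to
#' avoid division blow-up in empty grid corners.
#'
#' @param X,Y numeric 2D point matrices.
#' @param sigma bandwidth or `"median"`.
#' @param grid grid axes as in [witness_function()].
#' @param n_boot number of bootstrap resamples (default 200, >= 50).
#' @param seed optional RNG seed.
#' @param var_floor_rel relative variance floor (default 1e-12).
#' @return a `"witness_field"` with additional entries `s` (S matrix),
#'   `witness_mean`, `witness_var`, `n_boot`.
#' @export
s_statistic_map <- function(X, Y, sigma = "median", grid = NULL,
                            n_boot = 200L, seed = NULL,
                            var_floor_rel = 1e-12) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (n_boot < 50L) stop("n_boot must be >= 50")
  if (identical(sigma, "median")) sigma <- median_bandwidth(rbind(X, Y))
  if (is.null(grid)) grid <- latent_grid(rbind(X, Y))
  G <- as.matrix(expand.grid(x = grid$x, y = grid$y))
  Kx <- gaussian_kernel_matrix(X, G, sigma)   # m x |G|
  Ky <- gaussian_kernel_matrix(Y, G, sigma)
  m <- nrow(X); n <- nrow(Y)
  with_seed(seed, {
    acc <- matrix(0, n_boot, nrow(G))
    for (b in seq_len(n_boot)) {
      ix <- sample.int(m, m, replace = TRUE)
      iy <- sample.int(n, n, replace = TRUE)
      acc[b, ] <- colMeans(Kx[ix, , drop = FALSE]) -
                  colMeans(Ky[iy, , drop = FALSE])
    }
    mu <- colMeans(acc)
    v <- apply(acc, 2L, stats::var)
    if (all(v == 0)) stop("degenerate bootstrap: witness variance is zero everywhere")
    floor_v <- var_floor_rel * max(mu^2)
    n_floored <- sum(v < floor_v)
    if (n_floored > 0L)
      message(sprintf("S statistic: variance floored at %d of %d grid points",
                      n_floored, length(v)))
    s <- mu^2 / pmax(v, floor_v)
    nx <- length(grid$x)
    structure(list(x = grid$x, y = grid$y,
                   witness = matrix(colMeans(Kx) - colMeans(Ky), nx),
                   witness_mean = matrix(mu, nx),
                   witness_var = matrix(v, nx),
                   s = matrix(s, nx),
                   sigma = sigma, n_boot = n_boot),
              class = "witness_field")
  })
}

## 4-connected component labelling of a logical matrix (flood fill).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        pi <- p[1L]; pj <- p[2L]
        if (pi < 1L || pj < 1L || pi > nr || pj > nc) next
        if (!mask[pi, pj] || lab[pi, pj] != 0L) next
        lab[pi, pj] <- cur
        stack <- c(stack, list(c(pi - 1L, pj), c(pi + 1L, pj),
                               c(pi, pj - 1L), c(pi, pj + 1L)))
      }
    }
  }
  lab
}

#' Critical regions of a comparison
#'
#' Extracts, for each condition, the connected latent region that is most
#' responsible for the detected difference: the connected component of
#' {S >= threshold_frac * max S} containing the largest S value among grid
#' points where that condition's witness sign predominates (positive witness
#' for the first sample, negative for the second).
#'
#' @param field a `"witness_field"` from [s_statistic_map()].
#' @param threshold_frac fraction of the S maximum (default 3/4).
#' @return list with one entry per condition (`X`, `Y`), each a list with
#'   the logical grid `mask`, the `peak` coordinates and its `s_max`; an
#'   empty mask (with a warning) when that condition has no super-threshold
#'   point.
#' @export
critical_region <- function(field, threshold_frac = 0.75) {
  if (is.null(field$s)) stop("field has no S statistic: use s_statistic_map()")
  s <- field$s
  if (max(s) <= 0 || diff(range(s)) == 0) {
    warning("flat S field: empty critical regions")
    empty <- list(mask = matrix(FALSE, nrow(s), ncol(s)), peak = NULL, s_max = NA_real_)
    return(list(X = empty, Y = empty))
  }
  thr <- threshold_frac * max(s)
  super <- s >= thr
  lab <- label_components(super)
  w <- field$witness_mean %||% field$witness
  one_side <- function(sign_w) {
    side <- super & (sign(w) == sign_w)
    if (!any(side)) {
      warning("no critical region for one condition (no super-threshold point)")
      return(list(mask = matrix(FALSE, nrow(s), ncol(s)), peak = NULL,
                  s_max = NA_real_))
    }
    peak_idx <- which(side & s == max(s[side]), arr.ind = TRUE)[1L, ]
    comp <- lab == lab[peak_idx[1L], peak_idx[2L]]
    mask <- comp & (sign(w) == sign_w)
    list(mask = mask,
         peak = c(x = field$x[peak_idx[1L]], y = field$y[peak_idx[2L]]),
         s_max = s[peak_idx[1L], peak_idx[2L]])
  }
  list(X = one_side(1), Y = one_side(-1))
}

#' Nearest trajectories to a latent point
#'
#' Ranks trajectories by Euclidean distance of their latent vectors to a
#' query point, e.g. to display the trajectories most representative of a
#' critical region. Ties are broken by ascending trajectory id.
#'
#' @param point numeric query vector.
#' @param latents numeric matrix of latent vectors with row names as ids (or
#'   a data.frame containing matching columns).
#' @param ids trajectory ids (defaults to row names).
#' @param count number of neighbours (default 16).
#' @return character vector of the `count` nearest trajectory ids.
#' @export
nearest_trajectories <- function(point, latents, ids = rownames(latents),
                                 count = 16L) {
  latents <- as.matrix(latents)
  if (count < 1L) stop("count must be >= 1")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(latents)))
  if (count > nrow(latents)) {
    warning("count exceeds the number of trajectories: returning all")
    count <- nrow(latents)
  }
  d <- sqrt(colSums((t(latents) - as.numeric(point))^2))
  ids[order(d, ids)[seq_len(count)]]
}
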