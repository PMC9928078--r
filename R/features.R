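#' Effective diffusivity of a trajectory
#'
#' Apparent diffusion coefficient estimated from the sample variance of the
#' single-time-lapse displacements:
#' \deqn{\hat D = \sum_{i=1}^{N} \|\Delta r_i - \mu\|^2 / [4 (N-1) \Delta t],}
#' where \eqn{\Delta r_i} are the N displacements between consecutive
#' positions and \eqn{\mu} their mean. Here N counts displacements (a
#' trajectory of P points has N = P - 1), so at least two displacements
#' (P >= 3) are required.
#'
#' @param t a [trajectory()].
#' @return effective diffusivity in um^2/s (non-negative).
#' @export
effective_diffusivity <- function(t) {
  d <- displacements(t)
  n <- nrow(d)
  if (n < 2L) stop("effective diffusivity needs at least 2 displacements")
  mu <- colMeans(d)
  ss <- sum((d[, 1L] - mu[1L])^2 + (d[, 2L] - mu[2L])^2)
  ss / (4 * (n - 1) * t$dt)
}

## Katz fractal dimension of a planar path:
## FD = log10(n) / (log10(n) + log10(d / L)) with L the total path length,
## d the maximal distance from the first point and n the number of steps.
katz_fd <- function(pos) {
  d <- diff(pos)
  L <- sum(sqrt(rowSums(d^2)))
  n <- nrow(d)
  if (L == 0) return(1)
  dist0 <- sqrt(rowSums(sweep(pos, 2, pos[1L, ])^2))
  dmax <- max(dist0)
  if (dmax == 0) return(1)
  log10(n) / (log10(n) + log10(dmax / L))
}

## area of the convex hull of the positions (0 for collinear points)
hull_area <- function(pos) {
  pos <- unique(pos)
  if (nrow(pos) < 3L) return(0)
  h <- grDevices::chull(pos)
  v <- pos[h, , drop = FALSE]
  x <- v[, 1L]; y <- v[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

## asymmetry = 1 - lambda_min / lambda_max of the gyration tensor
gyration_asymmetry <- function(pos) {
  c0 <- sweep(pos, 2, colMeans(pos))
  g <- crossprod(c0) / nrow(pos)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] <= 0) return(0)
  1 - ev[2L] / ev[1L]
}

#' Classical per-trajectory descriptors
#'
#' The four analytical features used as baselines against the learnt latent
#' representation: log10 effective diffusivity, Katz fractal dimension,
#' convex-hull area and gyration-tensor asymmetry (1 minus the ratio of the
#' smaller to the larger eigenvalue; 1 for a perfectly straight path, 0 for
#' an isotropic cloud).
#'
#' @param t a [trajectory()] with at least 4 points.
#' @param log_d_floor sentinel returned for log10(D) when the effective
#'   diffusivity is exactly zero.
#' @return named numeric vector
#'   `c(log10_D, fractal_dim, hull_area, asymmetry)`.
#' @export
classical_features <- function(t, log_d_floor = -12) {
  pos <- t$positions
  if (nrow(pos) < 4L) stop("classical features need at least 4 points")
  D <- effective_diffusivity(t)
  logD <- if (D > 0) log10(D) else {
    warning("zero effective diffusivity: log10(D) floored")
    log_d_floor
  }
  c(log10_D = logD, fractal_dim = katz_fd(pos), hull_area = hull_area(pos),
    asymmetry = gyration_asymmetry(pos))
}

#' Classical feature matrix for a trajectory group
#'
#' @param group a [trajectory_group()].
#' @return numeric matrix, one row per trajectory, with the columns of
#'   [classical_features()]; row names are the track ids.
#' @export
classical_feature_matrix <- function(group) {
  stopifnot(inherits(group, "trajectory_group"))
  m <- t(vapply(group$trajectories, classical_features, numeric(4)))
  rownames(m) <- vapply(group$trajectories, function(t) t$track_id, character(1))
  m
}
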