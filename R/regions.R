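#' Construct a region mask
#'
#' Holds sub-cellular regions (e.g. synapse outlines) as simple polygons in
#' the same micrometre coordinate frame as the trajectories.
#'
#' @param regions named list; each element a numeric matrix of polygon
#'   vertices (2 columns, um). Names are the region ids.
#' @return an object of class `"region_mask"`.
#' @export
region_mask <- function(regions = list()) {
  if (length(regions)) {
    if (is.null(names(regions)) || anyDuplicated(names(regions)))
      stop("regions must be uniquely named")
    regions <- lapply(regions, function(p) {
      p <- as.matrix(p)
      if (ncol(p) != 2L || nrow(p) < 3L || !all(is.finite(p)))
        stop("each region must be a finite matrix of >= 3 vertices")
      p
    })
  }
  structure(list(regions = regions), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d region(s)\n", length(x$regions)))
  invisible(x)
}

points_in_polygon <- function(pts, poly) {
  ## mgcv::in.out expects the boundary as a closed loop
  bnd <- rbind(poly, poly[1L, , drop = FALSE])
  mgcv::in.out(bnd, pts)
}

#' Split a trajectory group by region membership
#'
#' A trajectory is assigned to a region when strictly more than half of its
#' localisations fall inside that region's polygon; otherwise it is
#' "outside". Ties (exactly half) and trajectories whose localisations are
#' split across regions without a strict majority in any single one count as
#' outside. Inside trajectories gain a `region_id` metadata field.
#'
#' @param group a [trajectory_group()].
#' @param mask a [region_mask()].
#' @return list with elements `inside` and `outside`, each a
#'   [trajectory_group()] or `NULL` when empty.
#' @export
assign_regions <- function(group, mask) {
  stopifnot(inherits(group, "trajectory_group"), inherits(mask, "region_mask"))
  if (!length(mask$regions)) {
    warning("empty region mask: all trajectories assigned outside")
    return(list(inside = NULL, outside = group))
  }
  inside <- list(); outside <- list()
  for (t in group$trajectories) {
    n <- nrow(t$positions)
    hit <- NULL
    for (rid in names(mask$regions)) {
      n_in <- sum(points_in_polygon(t$positions, mask$regions[[rid]]))
      if (n_in > n / 2) { hit <- rid; break }  # strict majority in one region
    }
    if (is.null(hit)) {
      outside[[length(outside) + 1L]] <- t
    } else {
      t$meta$region_id <- hit
      inside[[length(inside) + 1L]] <- t
    }
  }
  list(
    inside = if (length(inside))
      trajectory_group(inside, paste0(group$label, ":inside")) else NULL,
    outside = if (length(outside))
      trajectory_group(outside, paste0(group$label, ":outside")) else NULL
  )
}

#' Extract dense regions from a localisation cloud
#'
#' Estimates the localisation density with an isotropic Gaussian kernel on a
#' regular grid and returns the connected components of the super-level set
#' at a fraction of the maximum density, as polygonal contours. Defaults
#' follow the synaptic-region convention: 150 nm kernel bandwidth and a
#' threshold of one tenth of the maximum density.
#'
#' @param localizations numeric matrix (>= 10 rows, 2 columns, um).
#' @param bandwidth Gaussian kernel standard deviation in um (default 0.150).
#' @param threshold_frac density threshold as a fraction of the maximum,
#'   in (0, 1) (default 0.1).
#' @param cell grid cell size in um; defaults to `bandwidth / 3`, fine enough
#'   to resolve the kernel.
#' @return a [region_mask()] with one polygon per connected dense component.
#' @export
extract_dense_regions <- function(localizations, bandwidth = 0.150,
                                  threshold_frac = 0.1,
                                  cell = bandwidth / 3) {
  pts <- as.matrix(localizations)
  if (nrow(pts) < 10L) stop("need at least 10 localisations")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must be in (0, 1)")
  rx <- range(pts[, 1L]); ry <- range(pts[, 2L])
  if (diff(rx) == 0 && diff(ry) == 0)
    stop("all localisations identical: degenerate single region")
  pad <- 3 * bandwidth
  gx <- seq(rx[1L] - pad, rx[2L] + pad, by = cell)
  gy <- seq(ry[1L] - pad, ry[2L] + pad, by = cell)
  ## separable Gaussian KDE: density(x, y) = sum_i phi(x - xi) phi(y - yi)
  kx <- stats::dnorm(outer(gx, pts[, 1L], "-"), sd = bandwidth)
  ky <- stats::dnorm(outer(gy, pts[, 2L], "-"), sd = bandwidth)
  dens <- tcrossprod(kx, ky)          # |gx| x |gy|, up to a constant factor
  thr <- threshold_frac * max(dens)
  cl <- grDevices::contourLines(gx, gy, dens, levels = thr)
  if (!length(cl)) stop("no dense region found at this threshold")
  regions <- lapply(cl, function(c) cbind(c$x, c$y))
  names(regions) <- sprintf("region_%d", seq_along(regions))
  region_mask(regions)
}
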