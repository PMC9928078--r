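#' Causal edge wiring of a trajectory graph
#'
#' Each node i (1-based) receives edges from the past nodes
#' i - floor(gamma^j), j = 0..k-1, with gamma = (i - 1)^(1/(k-1)), after
#' removal of duplicates; trajectories shorter than k connect every node to
#' all of its predecessors. This gives recent points dense connections and
#' distant points sparse, geometrically spaced ones, with in-degree at most
#' k.
#'
#' @param N number of nodes (>= 2).
#' @param k maximal in-degree (default 10).
#' @return integer matrix with columns `src`, `dst` (src < dst), ordered by
#'   dst then src.
#' @export
build_edge_index <- function(N, k = 10L) {
  N <- as.integer(N); k <- as.integer(k)
  if (N < 2L) stop("need at least 2 nodes")
  if (k < 2L) stop("k must be >= 2")
  src <- integer(0); dst <- integer(0)
  for (i in 2:N) {
    if (N < k) {
      s <- seq_len(i - 1L)
    } else {
      gamma <- (i - 1)^(1 / (k - 1))
      ## tiny epsilon guards floor() against 19^(9/9) = 18.999... roundoff
      offs <- unique(pmax(1L, as.integer(floor(gamma^(0:(k - 1L)) + 1e-9))))
      s <- unique(i - offs[offs <= i - 1L])
    }
    s <- sort(s)
    src <- c(src, s); dst <- c(dst, rep.int(i, length(s)))
  }
  cbind(src = src, dst = dst)
}

#' Node features of a trajectory graph
#'
#' Six scale-free features per node i: normalised time (i-1)/(N-1); the sums
#' of step sizes to the powers 1, 2 and 4 up to point i, each normalised by
#' i * s^p; the distance to the origin |r_i - r_1| / s; and the running
#' maximum of that distance. The global scale s (root-mean-square one-step
#' displacement) is factored out so that features carry no absolute scale.
#' The first node's row is all zeros.
#'
#' @param t a [trajectory()].
#' @param scale global scale s (um); see [trajectory_to_graph()].
#' @return N x 6 numeric matrix.
#' @export
node_features <- function(t, scale) {
  if (scale <= 0) stop("degenerate trajectory: zero global scale")
  pos <- t$positions
  N <- nrow(pos)
  step <- sqrt(rowSums(diff(pos)^2))       # |dr_j|, j = 2..N (length N-1)
  cs1 <- c(0, cumsum(step / scale))
  cs2 <- c(0, cumsum((step / scale)^2))
  cs4 <- c(0, cumsum((step / scale)^4))
  i <- seq_len(N)
  dist0 <- sqrt(rowSums(sweep(pos, 2, pos[1L, ])^2)) / scale
  out <- cbind((i - 1) / (N - 1), cs1 / i, cs2 / i, cs4 / i, dist0, cummax(dist0))
  dimnames(out) <- list(NULL, c("t_norm", "s1", "s2", "s4", "dist0", "maxdist0"))
  out
}

#' Edge features of a trajectory graph
#'
#' Six features for an edge j -> i: normalised time difference (i-j)/(N-1);
#' normalised distance |r_i - r_j| / s; sums of step sizes to the powers 1,
#' 2 and 4 over the steps between j and i, normalised by (i-j) * s^p; and
#' the correlation (cosine) of the displacements arriving at j and at i
#' (0 when either is undefined or zero).
#'
#' @param t a [trajectory()].
#' @param edges edge matrix from [build_edge_index()].
#' @param scale global scale s.
#' @return |E| x 6 numeric matrix.
#' @export
edge_features <- function(t, edges, scale) {
  if (scale <= 0) stop("degenerate trajectory: zero global scale")
  pos <- t$positions
  N <- nrow(pos)
  d <- diff(pos)                            # row j-1 = displacement into j
  step <- sqrt(rowSums(d^2))
  cs1 <- c(0, cumsum(step / scale))
  cs2 <- c(0, cumsum((step / scale)^2))
  cs4 <- c(0, cumsum((step / scale)^4))
  src <- edges[, 1L]; dst <- edges[, 2L]
  span <- dst - src
  dist <- sqrt(rowSums((pos[dst, , drop = FALSE] - pos[src, , drop = FALSE])^2)) / scale
  ## displacement arriving at node i is d[i-1, ]; undefined for node 1
  corr <- numeric(nrow(edges))
  ok <- src >= 2L
  if (any(ok)) {
    a <- d[src[ok] - 1L, , drop = FALSE]
    b <- d[dst[ok] - 1L, , drop = FALSE]
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    cc <- rowSums(a * b) / (na * nb)
    cc[!is.finite(cc)] <- 0
    corr[ok] <- cc
  }
  out <- cbind(span / (N - 1), dist,
               (cs1[dst] - cs1[src]) / span,
               (cs2[dst] - cs2[src]) / span,
               (cs4[dst] - cs4[src]) / span,
               corr)
  dimnames(out) <- list(NULL, c("dt_norm", "dist", "s1", "s2", "s4", "corr"))
  out
}

#' Convert a trajectory into its feature graph
#'
#' Assembles the directed graph representation consumed by the encoder:
#' causal wiring from [build_edge_index()], six node and six edge features,
#' and a scalar global scale. The scale s is the root-mean-square one-step
#' displacement; feature matrices are invariant under rigid motions and
#' under dilation of the positions (a dilation by c only shifts the stored
#' `scale` field, log10(s), by log10(c)).
#'
#' @param t a [trajectory()].
#' @param k maximal in-degree (default 10).
#' @return an object of class `"traj_graph"`: list with `num_nodes`,
#'   `edges`, `node_features`, `edge_features`, `scale` (log10 s).
#' @export
trajectory_to_graph <- function(t, k = 10L) {
  stopifnot(inherits(t, "trajectory"))
  step2 <- rowSums(diff(t$positions)^2)
  s <- sqrt(mean(step2))
  if (s <= 0) stop("degenerate trajectory: all positions identical")
  edges <- build_edge_index(nrow(t$positions), k)
  structure(
    list(num_nodes = nrow(t$positions),
         edges = edges,
         node_features = node_features(t, s),
         edge_features = edge_features(t, edges, s),
         scale = log10(s),
         track_id = t$track_id),
    class = "traj_graph"
  )
}

#' @export
print.traj_graph <- function(x, ...) {
  cat(sprintf("<traj_graph '%s'> %d nodes, %d edges, log10 scale %.3f\n",
              x$track_id, x$num_nodes, nrow(x$edges), x$scale))
  invisible(x)
}

## Concatenate a list of traj_graphs into one batch with global node indices.
batch_graphs <- function(graphs) {
  nn <- vapply(graphs, function(g) g$num_nodes, integer(1))
  offs <- cumsum(c(0L, nn[-length(nn)]))
  edges <- do.call(rbind, Map(function(g, o) g$edges + o, graphs, offs))
  list(
    X = do.call(rbind, lapply(graphs, function(g) g$node_features)),
    E = do.call(rbind, lapply(graphs, function(g) g$edge_features)),
    src = edges[, 1L], dst = edges[, 2L],
    graph_id = rep.int(seq_along(graphs), nn),
    scale = vapply(graphs, function(g) g$scale, numeric(1)),
    n_graphs = length(graphs), n_nodes = sum(nn)
  )
}
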