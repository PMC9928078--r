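#' Fit a frozen parametric 2D projection of the latent space
#'
#' Learns a reusable map from the 16-dimensional latent space to a 2D plane
#' for visualisation and testing. The map is parametric and trained once,
#' on simulated latent vectors only, then frozen: applying it to new
#' (e.g. experimental) data requires no refit and is deterministic. It is
#' built by distilling a non-parametric 2D embedding of a landmark subsample
#' of the simulated latents (classical metric MDS of their pairwise
#' distances) into a small regression network, which then extends the
#' embedding to arbitrary points.
#'
#' @param latents numeric matrix of simulated latent vectors (>= 1e4 rows),
#'   or an [encode()] data.frame.
#' @param seed RNG seed (landmark choice, network initialisation, batches).
#' @param n_landmarks landmark subsample size for the non-parametric
#'   embedding (default 2000).
#' @param hidden hidden widths of the distillation network.
#' @param epochs,batch_size,lr training hyper-parameters of the
#'   distillation fit.
#' @return an object of class `"latent_projection"`; apply with
#'   [project_latent()] or attach to an encoder via
#'   `model$projection <- ...` so that [encode()] reports `proj1`/`proj2`.
#' @export
fit_projection_2d <- function(latents, seed = 1L, n_landmarks = 2000L,
                              hidden = c(32L, 32L), epochs = 200L,
                              batch_size = 256L, lr = 1e-3) {
  if (is.data.frame(latents)) latents <- latent_matrix(latents, "16d")
  latents <- as.matrix(latents)
  if (nrow(latents) < 1e4)
    stop("fit the projection on at least 1e4 simulated latent vectors")
  seeds <- derive_seeds(seed, 3L)
  ctr <- colMeans(latents); scl <- pmax(apply(latents, 2L, stats::sd), 1e-8)
  Z <- sweep(sweep(latents, 2L, ctr), 2L, scl, "/")
  land <- with_seed(seeds[1L], sample.int(nrow(Z), min(n_landmarks, nrow(Z))))
  emb <- stats::cmdscale(stats::dist(Z[land, , drop = FALSE]), k = 2L)
  ## distill the landmark embedding into a regression network
  sizes <- c(ncol(Z), hidden, 2L)
  p <- with_seed(seeds[2L], mlp_init(sizes))
  st <- adam_init(p)
  Xl <- Z[land, , drop = FALSE]
  n <- nrow(Xl)
  with_seed(seeds[3L], {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1L, n)]
        acts <- mlp_fwd(p, Xl[sel, , drop = FALSE])
        pred <- acts[[length(acts)]]
        d <- 2 * (pred - emb[sel, , drop = FALSE]) / length(sel)
        bw <- mlp_bwd(p, acts, d)
        up <- adam_step(p, bw$grads, st, lr = lr)
        p <- up$params; st <- up$state
      }
    }
  })
  acts <- mlp_fwd(p, Xl)
  mse <- mean((acts[[length(acts)]] - emb)^2)
  structure(list(params = p, center = ctr, scale = scl, sizes = sizes,
                 train_mse = mse, n_landmarks = length(land), seed = seed),
            class = "latent_projection")
}

#' Apply a frozen 2D projection
#'
#' @param proj a `"latent_projection"` from [fit_projection_2d()].
#' @param latents numeric matrix of latent vectors (or [encode()]
#'   data.frame).
#' @return matrix with 2 columns (projected coordinates).
#' @export
project_latent <- function(proj, latents) {
  stopifnot(inherits(proj, "latent_projection"))
  if (is.data.frame(latents)) latents <- latent_matrix(latents, "16d")
  Z <- sweep(sweep(as.matrix(latents), 2L, proj$center), 2L, proj$scale, "/")
  acts <- mlp_fwd(proj$params, Z)
  out <- acts[[length(acts)]]
  colnames(out) <- c("proj1", "proj2")
  out
}

#' @export
print.latent_projection <- function(x, ...) {
  cat(sprintf("<latent_projection> %d -> 2, distilled from %d landmarks (fit mse %.4g)\n",
              x$sizes[1L], x$n_landmarks, x$train_mse))
  invisible(x)
}
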