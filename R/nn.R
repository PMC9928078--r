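## Minimal dense-layer toolkit used by the graph encoder and the 2D
## projection network: parameter initialisation, Adam, and scatter/gather
## helpers for message passing. Everything operates on plain matrices so
## that the whole network runs on BLAS.

relu <- function(x) x * (x > 0)

init_mat <- function(n_in, n_out, gain = 2) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(gain / n_in)), n_in, n_out)
}

init_vec <- function(n) numeric(n)

## sum rows of M into n bins given by idx (bins absent from idx stay zero)
scatter_sum <- function(M, idx, n) {
  out <- matrix(0, n, ncol(M))
  rs <- rowsum(M, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

## x %*% W + b (b recycled over rows)
affine <- function(x, W, b) sweep(x %*% W, 2L, b, "+")

## One Adam step over a flat named list of parameter arrays.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

## ---- generic multilayer perceptron (used by heads and the projector) ----

mlp_init <- function(sizes, out_gain = 1) {
  p <- list()
  L <- length(sizes) - 1L
  for (l in seq_len(L)) {
    gain <- if (l == L) out_gain else 2
    p[[paste0("W", l)]] <- init_mat(sizes[l], sizes[l + 1L], gain)
    p[[paste0("b", l)]] <- init_vec(sizes[l + 1L])
  }
  p
}

## forward with ReLU on hidden layers, linear output; returns activations
mlp_fwd <- function(p, x) {
  L <- length(p) / 2L
  acts <- vector("list", L + 1L)
  acts[[1L]] <- x
  for (l in seq_len(L)) {
    z <- affine(acts[[l]], p[[paste0("W", l)]], p[[paste0("b", l)]])
    acts[[l + 1L]] <- if (l < L) relu(z) else z
  }
  acts
}

## backward: given d(out), returns list(dx, grads)
mlp_bwd <- function(p, acts, dout) {
  L <- length(p) / 2L
  g <- list()
  d <- dout
  for (l in rev(seq_len(L))) {
    if (l < L) d <- d * (acts[[l + 1L]] > 0)
    g[[paste0("W", l)]] <- crossprod(acts[[l]], d)
    g[[paste0("b", l)]] <- colSums(d)
    d <- tcrossprod(d, p[[paste0("W", l)]])
  }
  list(dx = d, grads = g)
}
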