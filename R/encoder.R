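#' Encoder configuration
#'
#' Architecture and training hyper-parameters of the graph neural encoder.
#' Defaults match the reference architecture: node features embedded to 10
#' dimensions and edge features to 16 by perceptrons, three
#' edge-conditioned GIN-style convolution layers with 32 channels,
#' attention pooling, concatenation of the scalar trajectory scale, and a
#' perceptron producing a 16-dimensional latent vector feeding two task
#' heads (anomalous-exponent regression and 5-class model classification,
#' hidden widths 64 and 32).
#'
#' @param node_embed_dim node embedding width (default 10).
#' @param edge_embed_dim edge embedding width (default 16).
#' @param conv_layers number of convolution layers (default 3).
#' @param conv_channels convolution width (default 32).
#' @param latent_dim latent width (default 16).
#' @param head_hidden hidden widths of the task heads.
#' @param embed_hidden hidden width of the node/edge embedding perceptrons.
#' @param latent_hidden hidden width of the latent perceptron.
#' @param gate_dim width of the attention gate.
#' @param k maximal in-degree of the trajectory graphs.
#' @param n_train number of simulated trajectories processed during
#'   training (1e5 is a practical single-CPU scale; more buys accuracy).
#' @param epochs passes over the simulated set (`n_train` counts
#'   trajectories processed in total, i.e. unique trajectories x epochs).
#' @param batch_size graphs per gradient step.
#' @param lr Adam learning rate.
#' @return an object of class `"encoder_config"`.
#' @export
encoder_config <- function(node_embed_dim = 10L, edge_embed_dim = 16L,
                           conv_layers = 3L, conv_channels = 32L,
                           latent_dim = 16L, head_hidden = c(64L, 32L),
                           embed_hidden = 32L, latent_hidden = 64L,
                           gate_dim = 16L, k = 10L,
                           n_train = 1e5, epochs = 4L, batch_size = 128L,
                           lr = 1e-3) {
  cfg <- list(node_embed_dim = node_embed_dim, edge_embed_dim = edge_embed_dim,
              conv_layers = conv_layers, conv_channels = conv_channels,
              latent_dim = latent_dim, head_hidden = head_hidden,
              embed_hidden = embed_hidden, latent_hidden = latent_hidden,
              gate_dim = gate_dim, k = k, n_train = n_train, epochs = epochs,
              batch_size = batch_size, lr = lr)
  if (any(unlist(cfg[1:10]) <= 0)) stop("all dimensions must be positive")
  structure(cfg, class = "encoder_config")
}

ENCODER_VERSION <- "walkmmd-encoder-1"

## ---- parameter initialisation ------------------------------------------

encoder_init_params <- function(cfg) {
  C <- cfg$conv_channels
  p <- list(
    ## node / edge embedding perceptrons
    nW1 = init_mat(6L, cfg$embed_hidden), nb1 = init_vec(cfg$embed_hidden),
    nW2 = init_mat(cfg$embed_hidden, cfg$node_embed_dim, 1), nb2 = init_vec(cfg$node_embed_dim),
    eW1 = init_mat(6L, cfg$embed_hidden), eb1 = init_vec(cfg$embed_hidden),
    eW2 = init_mat(cfg$embed_hidden, cfg$edge_embed_dim, 1), eb2 = init_vec(cfg$edge_embed_dim)
  )
  d_in <- cfg$node_embed_dim
  for (l in seq_len(cfg$conv_layers)) {
    ## sum aggregation over ~k in-edges: shrink message weights accordingly
    p[[paste0("c", l, "_Wm")]] <- init_mat(d_in, C, gain = 2 / cfg$k)
    p[[paste0("c", l, "_We")]] <- init_mat(cfg$edge_embed_dim, C, gain = 2 / cfg$k)
    p[[paste0("c", l, "_bm")]] <- init_vec(C)
    p[[paste0("c", l, "_Ws")]] <- init_mat(d_in, C, 1)
    p[[paste0("c", l, "_bs")]] <- init_vec(C)
    p[[paste0("c", l, "_W2")]] <- init_mat(C, C)
    p[[paste0("c", l, "_b2")]] <- init_vec(C)
    d_in <- C
  }
  ## attention pooling gate
  p$gWg <- init_mat(C, cfg$gate_dim, 1); p$gbg <- init_vec(cfg$gate_dim)
  p$ga  <- init_mat(cfg$gate_dim, 1L, 1); p$gba <- 0
  ## latent perceptron (scale concatenated)
  p$lW1 <- init_mat(C + 1L, cfg$latent_hidden); p$lb1 <- init_vec(cfg$latent_hidden)
  p$lW2 <- init_mat(cfg$latent_hidden, cfg$latent_dim, 1); p$lb2 <- init_vec(cfg$latent_dim)
  ## task heads
  h <- cfg$head_hidden
  p$aW1 <- init_mat(cfg$latent_dim, h[1L]); p$ab1 <- init_vec(h[1L])
  p$aW2 <- init_mat(h[1L], h[2L]); p$ab2 <- init_vec(h[2L])
  p$aW3 <- init_mat(h[2L], 1L, 1); p$ab3 <- 0
  p$mW1 <- init_mat(cfg$latent_dim, h[1L]); p$mb1 <- init_vec(h[1L])
  p$mW2 <- init_mat(h[1L], h[2L]); p$mb2 <- init_vec(h[2L])
  p$mW3 <- init_mat(h[2L], 5L, 1); p$mb3 <- init_vec(5L)
  p
}

#' Build an untrained encoder model
#'
#' Initialises the encoder's parameters at random (reproducibly by seed).
#' Use [fit_encoder()] to build and train in one call.
#'
#' @param config an [encoder_config()].
#' @param seed RNG seed for the initialisation.
#' @return an object of class `"walkmmd_encoder"` (untrained).
#' @export
build_encoder <- function(config = encoder_config(), seed = 1L) {
  params <- with_seed(seed, encoder_init_params(config))
  structure(list(params = params, config = config, prior = NULL,
                 projection = NULL, log = NULL, trained = FALSE,
                 version = ENCODER_VERSION, seed = seed),
            class = "walkmmd_encoder")
}

## ---- forward pass -------------------------------------------------------

## batch: output of batch_graphs(). Returns latent, alpha_pred, probs and
## (when cache = TRUE) every intermediate needed by the backward pass.
encoder_forward <- function(p, cfg, batch, cache = FALSE) {
  ng <- batch$n_graphs; nn <- batch$n_nodes
  gid <- batch$graph_id
  ## embeddings
  nh <- relu(affine(batch$X, p$nW1, p$nb1))
  H0 <- affine(nh, p$nW2, p$nb2)
  eh <- relu(affine(batch$E, p$eW1, p$eb1))
  E16 <- affine(eh, p$eW2, p$eb2)
  ## convolutions
  H <- H0
  conv_cache <- vector("list", cfg$conv_layers)
  for (l in seq_len(cfg$conv_layers)) {
    Wm <- p[[paste0("c", l, "_Wm")]]; We <- p[[paste0("c", l, "_We")]]
    bm <- p[[paste0("c", l, "_bm")]]; Ws <- p[[paste0("c", l, "_Ws")]]
    bs <- p[[paste0("c", l, "_bs")]]; W2 <- p[[paste0("c", l, "_W2")]]
    b2 <- p[[paste0("c", l, "_b2")]]
    Hsrc <- H[batch$src, , drop = FALSE]
    Mpre <- sweep(Hsrc %*% Wm + E16 %*% We, 2L, bm, "+")
    M <- relu(Mpre)
    A <- scatter_sum(M, batch$dst, nn)
    P1 <- sweep(H %*% Ws + A, 2L, bs, "+")
    H1 <- relu(P1)
    Hn <- relu(affine(H1, W2, b2))
    if (cache) conv_cache[[l]] <- list(H_in = H, Mpre = Mpre, M = M, P1 = P1,
                                       H1 = H1, H_out = Hn)
    H <- Hn
  }
  ## attention pooling
  Tg <- tanh(affine(H, p$gWg, p$gbg))
  s <- drop(Tg %*% p$ga) + p$gba
  smax <- stats::ave(s, gid, FUN = max)
  ex <- exp(s - smax)
  denom <- stats::ave(ex, gid, FUN = sum)
  alpha_w <- ex / denom
  pooled <- rowsum(alpha_w * H, gid)          # ng x C (gid is 1..ng)
  z_in <- cbind(pooled, batch$scale)
  L1 <- relu(affine(z_in, p$lW1, p$lb1))
  latent <- affine(L1, p$lW2, p$lb2)
  ## heads
  A1 <- relu(affine(latent, p$aW1, p$ab1))
  A2 <- relu(affine(A1, p$aW2, p$ab2))
  alpha_pred <- drop(affine(A2, p$aW3, p$ab3))
  M1 <- relu(affine(latent, p$mW1, p$mb1))
  M2 <- relu(affine(M1, p$mW2, p$mb2))
  logits <- affine(M2, p$mW3, p$mb3)
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  out <- list(latent = latent, alpha_pred = alpha_pred, probs = probs)
  if (cache)
    out$cache <- list(nh = nh, H0 = H0, eh = eh, E16 = E16, conv = conv_cache,
                      H = H, Tg = Tg, alpha_w = alpha_w, pooled = pooled,
                      z_in = z_in, L1 = L1, latent = latent, A1 = A1, A2 = A2,
                      M1 = M1, M2 = M2, probs = probs, alpha_pred = alpha_pred)
  out
}

## ---- loss and backward pass --------------------------------------------

## targets: list(model_idx = integer in 1..5, alpha = numeric, alpha_mask =
## logical (FALSE for OU)). Loss = CE(model) + masked MSE(alpha).
encoder_loss_grads <- function(p, cfg, batch, targets) {
  fw <- encoder_forward(p, cfg, batch, cache = TRUE)
  ca <- fw$cache
  ng <- batch$n_graphs
  ## cross-entropy
  pr <- ca$probs
  idx <- cbind(seq_len(ng), targets$model_idx)
  ce <- -mean(log(pmax(pr[idx], 1e-12)))
  dlogits <- pr
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / ng
  ## masked mse
  msk <- targets$alpha_mask
  n_a <- max(sum(msk), 1L)
  resid <- (ca$alpha_pred - targets$alpha) * msk
  mse <- sum(resid^2) / n_a
  dalpha <- 2 * resid / n_a
  loss <- ce + mse

  g <- list()
  ## model head
  dM2 <- tcrossprod(dlogits, p$mW3)
  g$mW3 <- crossprod(ca$M2, dlogits); g$mb3 <- colSums(dlogits)
  dM1pre <- (dM2 * (ca$M2 > 0))
  g$mW2 <- crossprod(ca$M1, dM1pre); g$mb2 <- colSums(dM1pre)
  dM1 <- tcrossprod(dM1pre, p$mW2)
  dMin <- dM1 * (ca$M1 > 0)
  g$mW1 <- crossprod(ca$latent, dMin); g$mb1 <- colSums(dMin)
  dlatent <- tcrossprod(dMin, p$mW1)
  ## alpha head
  dA3 <- matrix(dalpha, ng, 1L)
  g$aW3 <- crossprod(ca$A2, dA3); g$ab3 <- sum(dA3)
  dA2 <- tcrossprod(dA3, p$aW3) * (ca$A2 > 0)
  g$aW2 <- crossprod(ca$A1, dA2); g$ab2 <- colSums(dA2)
  dA1 <- tcrossprod(dA2, p$aW2) * (ca$A1 > 0)
  g$aW1 <- crossprod(ca$latent, dA1); g$ab1 <- colSums(dA1)
  dlatent <- dlatent + tcrossprod(dA1, p$aW1)
  ## latent perceptron
  g$lW2 <- crossprod(ca$L1, dlatent); g$lb2 <- colSums(dlatent)
  dL1 <- tcrossprod(dlatent, p$lW2) * (ca$L1 > 0)
  g$lW1 <- crossprod(ca$z_in, dL1); g$lb1 <- colSums(dL1)
  dz <- tcrossprod(dL1, p$lW1)
  C <- cfg$conv_channels
  dpooled <- dz[, seq_len(C), drop = FALSE]
  ## attention pooling backward
  gid <- batch$graph_id
  H <- ca$H; aw <- ca$alpha_w
  dPn <- dpooled[gid, , drop = FALSE]         # per-node copy of dpooled
  dH <- aw * dPn
  dalpha_w <- rowSums(H * dPn)
  dot <- rowsum(aw * dalpha_w, gid)[gid, 1L]
  ds <- aw * (dalpha_w - dot)
  dTg <- outer(ds, drop(p$ga))
  g$ga <- crossprod(ca$Tg, matrix(ds)); g$gba <- sum(ds)
  dGpre <- dTg * (1 - ca$Tg^2)
  g$gWg <- crossprod(H, dGpre); g$gbg <- colSums(dGpre)
  dH <- dH + tcrossprod(dGpre, p$gWg)
  ## convolutions backward
  dE16 <- matrix(0, nrow(ca$E16), ncol(ca$E16))
  for (l in rev(seq_len(cfg$conv_layers))) {
    cc <- ca$conv[[l]]
    Wm <- p[[paste0("c", l, "_Wm")]]; We <- p[[paste0("c", l, "_We")]]
    Ws <- p[[paste0("c", l, "_Ws")]]; W2 <- p[[paste0("c", l, "_W2")]]
    dP2 <- dH * (cc$H_out > 0)
    g[[paste0("c", l, "_W2")]] <- crossprod(cc$H1, dP2)
    g[[paste0("c", l, "_b2")]] <- colSums(dP2)
    dH1 <- tcrossprod(dP2, W2)
    dP1 <- dH1 * (cc$H1 > 0)
    g[[paste0("c", l, "_Ws")]] <- crossprod(cc$H_in, dP1)
    g[[paste0("c", l, "_bs")]] <- colSums(dP1)
    dH_in <- tcrossprod(dP1, Ws)
    dA <- dP1
    dM <- dA[batch$dst, , drop = FALSE] * (cc$M > 0)
    g[[paste0("c", l, "_Wm")]] <- crossprod(cc$H_in[batch$src, , drop = FALSE], dM)
    g[[paste0("c", l, "_We")]] <- crossprod(ca$E16, dM)
    g[[paste0("c", l, "_bm")]] <- colSums(dM)
    dE16 <- dE16 + tcrossprod(dM, We)
    dH_in <- dH_in + scatter_sum(tcrossprod(dM, Wm), batch$src, batch$n_nodes)
    dH <- dH_in
  }
  ## embeddings backward
  g$nW2 <- crossprod(ca$nh, dH); g$nb2 <- colSums(dH)
  dnh <- tcrossprod(dH, p$nW2) * (ca$nh > 0)
  g$nW1 <- crossprod(batch$X, dnh); g$nb1 <- colSums(dnh)
  g$eW2 <- crossprod(ca$eh, dE16); g$eb2 <- colSums(dE16)
  deh <- tcrossprod(dE16, p$eW2) * (ca$eh > 0)
  g$eW1 <- crossprod(batch$E, deh); g$eb1 <- colSums(deh)

  list(loss = loss, ce = ce, mse = mse, grads = g)
}

## ---- training -----------------------------------------------------------

graph_targets <- function(group) {
  model <- vapply(group$trajectories, function(t) t$meta$model, character(1))
  alpha <- vapply(group$trajectories, function(t) t$meta$alpha %||% NA_real_,
                  numeric(1))
  midx <- match(model, MODEL_KINDS)
  msk <- model != "OU" & is.finite(alpha)
  alpha[!msk] <- 0
  list(model_idx = midx, alpha = alpha, alpha_mask = msk)
}

#' Fit the graph neural encoder by simulation-based inference
#'
#' Simulates labelled trajectories from the prior (uniform mixture over the
#' five models), converts them to feature graphs, and trains the encoder to
#' jointly predict the anomalous exponent (mean squared error, excluding OU
#' trajectories, which have no anomalous exponent) and the generative model
#' (cross-entropy over the five classes). The total loss is the unweighted
#' sum of the two task losses. After training the parameters are frozen;
#' the fitted model maps any trajectory to a 16-dimensional latent
#' summary-statistics vector via [encode()].
#'
#' @param prior a [sim_prior()]; stored in the model as the training
#'   snapshot.
#' @param config an [encoder_config()]; `n_train` is the total number of
#'   trajectory presentations (unique trajectories = n_train / epochs).
#' @param seed RNG seed controlling simulation, initialisation and batch
#'   order (end-to-end reproducible).
#' @param verbose print per-epoch losses.
#' @return an object of class `"walkmmd_encoder"` with elements `params`,
#'   `config`, `prior`, `log` (per-epoch losses), `projection` (`NULL`
#'   until [fit_projection_2d()] is attached).
#' @export
fit_encoder <- function(prior = sim_prior(), config = encoder_config(),
                        seed = 1L, verbose = interactive()) {
  stopifnot(inherits(prior, "sim_prior"), inherits(config, "encoder_config"))
  seeds <- derive_seeds(seed, 4L)
  n_unique <- max(as.integer(ceiling(config$n_train / config$epochs)),
                  config$batch_size)
  mix <- mixture_spec(stats::setNames(rep(1 / 5, 5), MODEL_KINDS))
  group <- generate_dataset(mix, n_unique, prior, seed = seeds[1L],
                            label = "train")
  graphs <- lapply(group$trajectories, trajectory_to_graph, k = config$k)
  targets <- graph_targets(group)
  model <- build_encoder(config, seed = seeds[2L])
  p <- model$params
  st <- adam_init(p)
  log <- data.frame(epoch = integer(0), loss = numeric(0), ce = numeric(0),
                    mse = numeric(0))
  with_seed(seeds[3L], {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_unique)
      losses <- ces <- mses <- numeric(0)
      for (start in seq(1L, n_unique, by = config$batch_size)) {
        sel <- ord[start:min(start + config$batch_size - 1L, n_unique)]
        if (length(sel) < 2L) next
        b <- batch_graphs(graphs[sel])
        tg <- list(model_idx = targets$model_idx[sel],
                   alpha = targets$alpha[sel],
                   alpha_mask = targets$alpha_mask[sel])
        lg <- encoder_loss_grads(p, config, b, tg)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged at epoch %d (loss = %g)", ep, lg$loss))
        up <- adam_step(p, lg$grads, st, lr = config$lr)
        p <- up$params; st <- up$state
        losses <- c(losses, lg$loss); ces <- c(ces, lg$ce); mses <- c(mses, lg$mse)
      }
      log <- rbind(log, data.frame(epoch = ep, loss = mean(losses),
                                   ce = mean(ces), mse = mean(mses)))
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.4f (ce %.4f, mse %.4f)",
                        ep, config$epochs, mean(losses), mean(ces), mean(mses)))
    }
  })
  model$params <- p
  model$prior <- prior
  model$log <- log
  model$trained <- TRUE
  model$seed <- seed
  model
}

#' @export
print.walkmmd_encoder <- function(x, ...) {
  cat(sprintf("<walkmmd_encoder> %s, latent dim %d, %s\n", x$version,
              x$config$latent_dim,
              if (x$trained) sprintf("trained (%d epochs, final loss %.4f)",
                                     nrow(x$log), x$log$loss[nrow(x$log)])
              else "untrained"))
  if (!is.null(x$projection)) cat("  2D projection attached (frozen)\n")
  invisible(x)
}

#' Encode trajectories into latent summary statistics
#'
#' Deterministic evaluation of the trained encoder on a trajectory group:
#' each trajectory is converted to its feature graph and mapped to its
#' 16-dimensional latent vector, predicted anomalous exponent and
#' model-class probabilities. When a frozen 2D projection is attached
#' (see [fit_projection_2d()]) the projected coordinates are included.
#' Degenerate trajectories (all positions identical) are skipped with a
#' message. Outputs do not depend on the batch composition.
#'
#' @param model a trained `"walkmmd_encoder"`.
#' @param group a [trajectory_group()] (or list of trajectories).
#' @param chunk number of graphs evaluated per batch.
#' @return data.frame with columns `track_id`, `group`, `length`,
#'   `latent1..latentK`, `pred_alpha`, `prob_<model>` for the five models,
#'   and `proj1`, `proj2` when a projection is attached.
#' @export
encode <- function(model, group, chunk = 512L) {
  stopifnot(inherits(model, "walkmmd_encoder"))
  if (!model$trained) warning("encoding with an untrained encoder")
  trajs <- if (inherits(group, "trajectory_group")) group$trajectories else group
  label <- if (inherits(group, "trajectory_group")) group$label else "group"
  graphs <- list(); keep <- logical(length(trajs))
  for (i in seq_along(trajs)) {
    g <- tryCatch(trajectory_to_graph(trajs[[i]], k = model$config$k),
                  error = function(e) NULL)
    if (is.null(g)) {
      message(sprintf("skipping degenerate trajectory '%s'", trajs[[i]]$track_id))
    } else {
      keep[i] <- TRUE
      graphs[[length(graphs) + 1L]] <- g
    }
  }
  if (!length(graphs)) stop("no encodable trajectory in the group")
  K <- model$config$latent_dim
  out <- vector("list", ceiling(length(graphs) / chunk))
  for (ci in seq_along(out)) {
    sel <- ((ci - 1L) * chunk + 1L):min(ci * chunk, length(graphs))
    fw <- encoder_forward(model$params, model$config, batch_graphs(graphs[sel]))
    out[[ci]] <- list(latent = fw$latent, alpha = fw$alpha_pred, probs = fw$probs)
  }
  latent <- do.call(rbind, lapply(out, `[[`, "latent"))
  colnames(latent) <- paste0("latent", seq_len(K))
  probs <- do.call(rbind, lapply(out, `[[`, "probs"))
  colnames(probs) <- paste0("prob_", MODEL_KINDS)
  df <- data.frame(
    track_id = vapply(trajs[keep], function(t) t$track_id, character(1)),
    group = label,
    length = vapply(trajs[keep], length, integer(1)),
    latent,
    pred_alpha = unlist(lapply(out, `[[`, "alpha")),
    probs,
    stringsAsFactors = FALSE
  )
  if (!is.null(model$projection)) {
    pr <- project_latent(model$projection, latent)
    df$proj1 <- pr[, 1L]; df$proj2 <- pr[, 2L]
  }
  df
}

#' @export
predict.walkmmd_encoder <- function(object, newdata, ...) encode(object, newdata, ...)

#' Extract the latent feature matrix from an encoding
#'
#' Pulls the 2D-projected (`"2d"`) or full 16-dimensional (`"16d"`) latent
#' coordinates out of an [encode()] data.frame as a numeric matrix with the
#' track ids as row names, ready for [mmd_test()] and friends.
#'
#' @param df data.frame returned by [encode()].
#' @param dims `"2d"` (default) or `"16d"`.
#' @return numeric matrix, one row per trajectory.
#' @export
latent_matrix <- function(df, dims = c("2d", "16d")) {
  dims <- match.arg(dims)
  cols <- if (dims == "2d") c("proj1", "proj2") else
    grep("^latent[0-9]+$", names(df), value = TRUE)
  if (!all(cols %in% names(df)))
    stop("requested latent columns absent (is the 2D projection attached?)")
  m <- as.matrix(df[, cols])
  rownames(m) <- df$track_id
  m
}

#' Save / load a fitted encoder
#'
#' Serialises the full model state (parameters, configuration, training
#' prior snapshot, projection, version tag) so that a reload reproduces
#' [encode()] outputs bit-exactly.
#'
#' @param model a `"walkmmd_encoder"`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "walkmmd_encoder"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable encoder model file: ", conditionMessage(e)))
  if (!inherits(obj, "walkmmd_encoder") ||
      !identical(obj$version, ENCODER_VERSION))
    stop("model file version mismatch (expected ", ENCODER_VERSION, ")")
  obj
}
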