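test_that("untrained encoder has the documented shapes and is seed-deterministic", {
  cfg <- encoder_config(n_train = 1000, epochs = 1L)
  m1 <- build_encoder(cfg, seed = 5)
  m2 <- build_encoder(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, build_encoder(cfg, seed = 6)$params))
  expect_false(m1$trained)
  g <- generate_dataset(uniform_mixture(), 7, sim_prior(), seed = 1)
  b <- walkmmd:::batch_graphs(lapply(g$trajectories, trajectory_to_graph))
  fw <- walkmmd:::encoder_forward(m1$params, cfg, b)
  expect_equal(dim(fw$latent), c(7L, 16L))
  expect_equal(dim(fw$probs), c(7L, 5L))
  expect_equal(unname(rowSums(fw$probs)), rep(1, 7), tolerance = 1e-12)
  expect_length(fw$alpha_pred, 7L)
  expect_true(all(is.finite(fw$latent)))
  expect_error(encoder_config(latent_dim = 0), "positive")
})

test_that("analytical gradients match central finite differences", {
  cfg <- encoder_config()
  m <- build_encoder(cfg, seed = 7)
  ## move to a generic point: ReLU pre-activations exactly at 0 (zero biases
  ## on the all-zero first node row) make the subgradient differ from the
  ## secant slope, so perturb every parameter off the kinks first
  set.seed(8)
  p <- lapply(m$params, function(x) x + stats::rnorm(length(x)) * 0.05)
  g <- generate_dataset(uniform_mixture(), 4, sim_prior(), seed = 2)
  b <- walkmmd:::batch_graphs(lapply(g$trajectories, trajectory_to_graph))
  tg <- walkmmd:::graph_targets(g)
  lg <- walkmmd:::encoder_loss_grads(p, cfg, b, tg)
  expect_true(is.finite(lg$loss))
  expect_setequal(names(lg$grads), names(p))
  loss_at <- function(pp) walkmmd:::encoder_loss_grads(pp, cfg, b, tg)$loss
  eps <- 1e-5
  set.seed(9)
  picks <- lapply(sample(names(p), 14), function(nm)
    list(nm = nm, i = sample.int(length(p[[nm]]), 1)))
  for (pk in picks) {
    pp <- p; pp[[pk$nm]][pk$i] <- pp[[pk$nm]][pk$i] + eps
    pm <- p; pm[[pk$nm]][pk$i] <- pm[[pk$nm]][pk$i] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    ana <- lg$grads[[pk$nm]][pk$i]
    expect_equal(ana, num, tolerance = 5e-2,
                 label = sprintf("d loss / d %s[%d] = %g (numeric %g)",
                                 pk$nm, pk$i, ana, num))
  }
})

test_that("training reduces the loss and records a log", {
  cfg <- encoder_config(n_train = 1536, epochs = 3L, batch_size = 128L)
  m <- fit_encoder(config = cfg, seed = 42, verbose = FALSE)
  expect_true(m$trained)
  expect_equal(nrow(m$log), 3L)
  expect_lt(m$log$loss[3L], m$log$loss[1L])
  ## end-to-end reproducibility
  m2 <- fit_encoder(config = cfg, seed = 42, verbose = FALSE)
  expect_identical(m$params, m2$params)
})

test_that("encode() is invariant to rigid motions and batch composition", {
  m <- trained_encoder()
  g <- generate_dataset(uniform_mixture(), 40, sim_prior(), seed = 3)
  df <- encode(m, g)
  expect_equal(nrow(df), 40L)
  expect_true(all(paste0("latent", 1:16) %in% names(df)))
  expect_true(all(paste0("prob_", MODEL_KINDS) %in% names(df)))
  ## rigid motion: rotate + translate every trajectory
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- lapply(g$trajectories, function(t)
    trajectory(sweep(t$positions %*% R, 2, c(-4, 9), "+"), t$dt,
               track_id = t$track_id))
  df_rot <- encode(m, rot)
  expect_equal(latent_matrix(df_rot, "16d"), latent_matrix(df, "16d"),
               tolerance = 1e-8)
  ## batch composition: reversed order and a tiny chunk size
  df_rev <- encode(m, rev(g$trajectories), chunk = 7L)
  df_rev <- df_rev[match(df$track_id, df_rev$track_id), ]
  expect_equal(unname(latent_matrix(df_rev, "16d")),
               unname(latent_matrix(df, "16d")), tolerance = 1e-10)
  expect_equal(df_rev$pred_alpha, df$pred_alpha, tolerance = 1e-10)
})

test_that("the frozen 2D projection is attached, finite and deterministic", {
  m <- trained_encoder()
  expect_s3_class(m$projection, "latent_projection")
  g <- generate_dataset(uniform_mixture(), 25, sim_prior(), seed = 4)
  df <- encode(m, g)
  expect_true(all(c("proj1", "proj2") %in% names(df)))
  P <- latent_matrix(df, "2d")
  expect_true(all(is.finite(P)))
  expect_identical(P, latent_matrix(encode(m, g), "2d"))
  ## the projection is a fixed map of the 16D latent
  L <- latent_matrix(df, "16d")
  expect_equal(unname(project_latent(m$projection, L)), unname(P),
               tolerance = 1e-12)
})

test_that("save/load round-trips the encoder bit-exactly", {
  m <- trained_encoder()
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  g <- generate_dataset(uniform_mixture(), 10, sim_prior(), seed = 5)
  expect_identical(encode(m2, g), encode(m, g))
  bad <- tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), "not a readable encoder model file")
  wrong <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), wrong)
  expect_error(load_model(wrong), "version mismatch")
  unlink(c(path, bad, wrong))
})

test_that("latents linearly separate slow from fast fBM", {
  m <- trained_encoder()
  prior <- sim_prior()
  mk <- function(alpha, seed) {
    ps <- sample_prior(prior, rep("fBM", 150L), 150L, seed = seed)
    ps$alpha <- alpha
    trajs <- lapply(seq_len(150L), function(i) {
      t <- simulate_trajectory("fBM", ps[i, ], dt = prior$dt, seed = seed * 1000 + i)
      add_localization_noise(t, ps$noise_sd[i], seed = seed * 2000 + i)
    })
    encode(m, trajs)
  }
  slow <- mk(0.4, 11); fast <- mk(1.6, 12)
  ## the regression head orders the two populations correctly ...
  expect_lt(mean(slow$pred_alpha), mean(fast$pred_alpha))
  ## ... and a linear probe on the 16D latent separates them well
  L <- rbind(latent_matrix(slow, "16d"), latent_matrix(fast, "16d"))
  y <- rep(c(0, 1), each = 150L)
  fit <- suppressWarnings(stats::glm.fit(cbind(1, L), y,
                                         family = stats::binomial()))
  acc <- mean((fit$fitted.values > 0.5) == y)
  expect_gt(acc, 0.85)
})
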