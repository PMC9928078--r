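test_that("prior draws honour the stated distributions", {
  prior <- sim_prior()
  draws <- sample_prior(prior, rep(MODEL_KINDS, length.out = 1e5), 1e5,
                        seed = 123)
  ## log-uniform lengths on [7, 25] have mean ~14 points
  expect_equal(round(mean(draws$N)), 14)
  expect_true(all(draws$N >= 7 & draws$N <= 25))
  ## log-normal diffusivity: mean and sd of log10(D / D0)
  expect_equal(mean(log10(draws$D)), -0.5, tolerance = 0.02)
  expect_equal(sd(log10(draws$D)), 0.5, tolerance = 0.02)
  ## noise sd uniform on [0.015, 0.040]
  expect_true(all(draws$noise_sd >= 0.015 & draws$noise_sd <= 0.040))
  expect_equal(mean(draws$noise_sd), 0.0275, tolerance = 0.001)
  ## theta only for OU, alpha never for OU
  expect_true(all(is.na(draws$theta[draws$model != "OU"])))
  expect_true(all(is.finite(draws$theta[draws$model == "OU"])))
  expect_true(all(is.na(draws$alpha[draws$model == "OU"])))
  ## determinism
  again <- sample_prior(prior, rep(MODEL_KINDS, length.out = 1e5), 1e5,
                        seed = 123)
  expect_identical(draws, again)
})

test_that("fBM with alpha = 1 has uncorrelated increments", {
  set.seed(8)
  num <- 0; den <- 0; n_pairs <- 0
  for (i in 1:2000) {
    t <- simulate_trajectory("fBM", list(N = 15, D = 1, alpha = 1))
    dx <- diff(t$positions[, 1L])
    num <- num + sum(dx[-1L] * dx[-length(dx)])
    den <- den + sum(dx^2)
    n_pairs <- n_pairs + length(dx) - 1L
  }
  r <- num / den
  expect_lt(abs(r), 3 / sqrt(n_pairs))
})

test_that("fBM increment autocorrelation has the fGn sign structure", {
  set.seed(9)
  lag1 <- function(alpha) {
    v <- replicate(1500, {
      dx <- diff(simulate_trajectory("fBM", list(N = 20, D = 1, alpha = alpha))$positions[, 1L])
      c(sum(dx[-1L] * dx[-length(dx)]), sum(dx^2))
    })
    sum(v[1, ]) / sum(v[2, ])
  }
  expect_lt(lag1(0.4), -0.05)   # subdiffusive fBM is anti-persistent
  expect_gt(lag1(1.6), 0.05)    # superdiffusive fBM is persistent
})

test_that("OU reaches its stationary variance and decays", {
  ## theta large (per time lapse): position variance ~ D * dt / theta
  set.seed(10)
  xs <- replicate(4000,
    simulate_trajectory("OU", list(N = 10, D = 1, theta = 5), dt = 0.0154)$positions[5L, ])
  v <- mean(apply(xs, 1L, var))
  expect_lt(abs(v / (1 * 0.0154 / 5) - 1), 0.1)
})

test_that("CTRW paths contain repeated consecutive positions", {
  set.seed(11)
  frac_repeat <- mean(replicate(300, {
    t <- simulate_trajectory("CTRW", list(N = 20, D = 1, alpha = 0.5))
    any(rowSums(abs(diff(t$positions))) == 0)
  }))
  expect_gt(frac_repeat, 0.5)   # waiting between jumps freezes the position
})

test_that("localisation noise has the requested magnitude", {
  base <- simulate_trajectory("fBM", list(N = 25, D = 1, alpha = 1), seed = 3)
  expect_identical(add_localization_noise(base, 0), base)
  set.seed(12)
  errs <- unlist(replicate(2000, {
    noisy <- add_localization_noise(base, 0.025)
    noisy$positions - noisy$meta$true_positions
  }))
  se <- 0.025 / sqrt(2 * length(errs))
  expect_lt(abs(sd(errs) - 0.025), 3 * se)
})

test_that("ensemble MSD recovers the nominal anomalous exponent", {
  ## parameter-recovery oracle: log-log regression of ensemble MSD vs lag
  set.seed(13)
  fit_exponent <- function(model, alpha, n_traj = 3000, N = 100) {
    msd <- matrix(0, n_traj, N - 1L)
    for (i in seq_len(n_traj)) {
      p <- simulate_trajectory(model, list(N = N, D = 1, alpha = alpha))$positions
      msd[i, ] <- rowSums((p[-1L, , drop = FALSE] -
                             matrix(p[1L, ], N - 1L, 2, byrow = TRUE))^2)
    }
    lags <- seq_len(N - 1L)
    unname(coef(lm(log(colMeans(msd)) ~ log(lags)))[2L])
  }
  cases <- list(c("fBM", 0.5), c("fBM", 1.5), c("sBM", 0.6), c("sBM", 1.4),
                c("LW", 1.5))
  for (cs in cases) {
    est <- fit_exponent(cs[1L], as.numeric(cs[2L]))
    expect_equal(est, as.numeric(cs[2L]), tolerance = 0.15,
                 label = sprintf("%s alpha=%s exponent %0.3f", cs[1L], cs[2L], est))
  }
})

test_that("ensemble MSD scales linearly with D", {
  set.seed(14)
  msd_at <- function(D) {
    mean(replicate(3000, {
      p <- simulate_trajectory("sBM", list(N = 10, D = D, alpha = 0.8))$positions
      sum((p[10L, ] - p[1L, ])^2)
    }))
  }
  expect_equal(msd_at(2) / msd_at(1), 2, tolerance = 0.15)
})

test_that("generated datasets are labelled, reproducible and well-mixed", {
  prior <- sim_prior()
  pure <- generate_dataset(mixture_spec(c(fBM = 1)), 100, prior, seed = 1)
  models <- vapply(pure$trajectories, function(t) t$meta$model, character(1))
  expect_true(all(models == "fBM"))
  mix <- mixture_spec(c(fBM = 0.5, sBM = 0.5))
  big <- generate_dataset(mix, 10000, prior, seed = 2)
  n_fbm <- sum(vapply(big$trajectories, function(t) t$meta$model,
                      character(1)) == "fBM")
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(n_fbm, ci[1L]); expect_lte(n_fbm, ci[2L])
  ## same seed -> identical dataset
  again <- generate_dataset(mix, 50, prior, seed = 9)
  once <- generate_dataset(mix, 50, prior, seed = 9)
  expect_identical(write_trajectories(once), write_trajectories(again))
  ## lengths respect the sampled N and positions are finite
  ns <- vapply(big$trajectories, length, integer(1))
  expect_true(all(ns >= 7 & ns <= 25))
  expect_true(all(vapply(big$trajectories,
                         function(t) all(is.finite(t$positions)), logical(1))))
  expect_error(mixture_spec(c(fBM = 0.6, sBM = 0.6)), "sum to 1")
})

test_that("model-specific validation rejects bad parameters", {
  expect_error(simulate_trajectory("XXX", list(N = 10, D = 1)), "unknown model")
  expect_error(simulate_trajectory("LW", list(N = 10, D = 1, alpha = 0.5)),
               "outside the LW range")
  expect_error(simulate_trajectory("CTRW", list(N = 10, D = 1, alpha = 1.5)),
               "outside the CTRW range")
})
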