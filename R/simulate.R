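## Trajectory simulators for the five canonical random-walk models.
## All models share the diffusivity scale: the per-dimension variance of a
## one-time-lapse displacement is 2*D*dt (exactly for fBM/sBM at the first
## step, in a matched-moment sense for OU/CTRW/LW).

## fractional Gaussian noise increments via exact Cholesky factorization of
## the autocovariance (trajectories are short, N <= ~25, so this is cheap
## and exact). H = alpha / 2.
fgn_increments <- function(n_steps, alpha, sigma2) {
  H <- alpha / 2
  lag <- 0:(n_steps - 1L)
  acov <- sigma2 / 2 * (abs(lag + 1)^(2 * H) - 2 * abs(lag)^(2 * H) +
                          abs(lag - 1)^(2 * H))
  C <- stats::toeplitz(acov)
  L <- t(chol(C + diag(1e-12 * sigma2, n_steps)))
  as.vector(L %*% stats::rnorm(n_steps))
}

sim_fbm <- function(N, D, alpha, dt) {
  s2 <- 2 * D * dt
  if (abs(alpha - 1) < 1e-12) {
    dx <- stats::rnorm(N - 1L, sd = sqrt(s2)); dy <- stats::rnorm(N - 1L, sd = sqrt(s2))
  } else {
    dx <- fgn_increments(N - 1L, alpha, s2)
    dy <- fgn_increments(N - 1L, alpha, s2)
  }
  cbind(cumsum(c(0, dx)), cumsum(c(0, dy)))
}

sim_sbm <- function(N, D, alpha, dt) {
  ## K_alpha = D * dt^(1 - alpha); Var(step i) = 2 K_alpha (t_i^a - t_{i-1}^a)
  t_grid <- (0:(N - 1L)) * dt
  v <- 2 * D * dt^(1 - alpha) * diff(t_grid^alpha)
  sd <- sqrt(v)
  cbind(cumsum(c(0, stats::rnorm(N - 1L, sd = sd))),
        cumsum(c(0, stats::rnorm(N - 1L, sd = sd))))
}

sim_ou <- function(N, D, theta, dt) {
  ## theta is a relaxation rate per time lapse; exact discretization with
  ## stationary start. Stationary per-dimension variance D*dt/theta gives
  ## one-step displacement variance -> 2*D*dt as theta -> 0.
  svar <- D * dt / theta
  a <- exp(-theta)
  innov_sd <- sqrt(svar * (1 - a^2))
  sim1 <- function() {
    x <- numeric(N)
    x[1L] <- stats::rnorm(1L, sd = sqrt(svar))
    for (i in 2:N) x[i] <- a * x[i - 1L] + stats::rnorm(1L, sd = innov_sd)
    x
  }
  cbind(sim1(), sim1())
}

sim_ctrw <- function(N, D, alpha, dt) {
  ## heavy-tailed waiting times psi(tau) ~ tau^(-1-alpha), tau >= dt/10;
  ## Gaussian jumps with per-dimension sd sqrt(2 D dt); position constant
  ## between jumps, sampled on the regular dt grid.
  t_end <- (N - 1L) * dt
  tau0 <- dt / 10
  times <- numeric(0); tt <- 0
  while (tt < t_end) {
    ## draw waits in blocks for speed
    w <- tau0 * stats::runif(16L)^(-1 / alpha)
    for (wi in w) {
      tt <- tt + wi
      if (tt >= t_end) break
      times <- c(times, tt)
    }
  }
  n_jumps <- length(times)
  sdj <- sqrt(2 * D * dt)
  jx <- c(0, cumsum(stats::rnorm(n_jumps, sd = sdj)))
  jy <- c(0, cumsum(stats::rnorm(n_jumps, sd = sdj)))
  grid <- (0:(N - 1L)) * dt
  idx <- findInterval(grid, times) + 1L
  cbind(jx[idx], jy[idx])
}

sim_lw <- function(N, D, alpha, dt) {
  ## Levy walk: constant-speed flights with heavy-tailed durations and
  ## uniform random directions. MSD exponent alpha in [1, 2] maps to the
  ## duration tail exponent sigma = 3 - alpha (alpha = 2: ballistic).
  t_end <- (N - 1L) * dt
  tau0 <- dt / 10
  v <- 2 * sqrt(D / dt)       # per-dim one-frame displacement variance 2 D dt
  sigma_tail <- 3 - alpha
  grid <- (0:(N - 1L)) * dt
  x <- numeric(N); y <- numeric(N)
  tt <- 0; px <- 0; py <- 0; i <- 2L
  x[1L] <- 0; y[1L] <- 0
  while (tt < t_end && i <= N) {
    dur <- if (sigma_tail <= 1.0001 && alpha >= 2 - 1e-9) t_end + 1 else
      tau0 * stats::runif(1L)^(-1 / sigma_tail)
    ang <- stats::runif(1L, 0, 2 * pi)
    vx <- v * cos(ang); vy <- v * sin(ang)
    t_next <- min(tt + dur, t_end)
    while (i <= N && grid[i] <= t_next + 1e-12) {
      x[i] <- px + vx * (grid[i] - tt)
      y[i] <- py + vy * (grid[i] - tt)
      i <- i + 1L
    }
    px <- px + vx * (t_next - tt); py <- py + vy * (t_next - tt)
    tt <- t_next
  }
  cbind(x, y)
}

#' Simulate a single trajectory
#'
#' Draws one trajectory from a canonical random-walk model at a regular time
#' lapse. Per-model contracts: fBM has stationary correlated Gaussian
#' increments with Hurst exponent alpha/2 and per-dimension one-step variance
#' 2 D dt; sBM has independent Gaussian increments with variance
#' 2 K_alpha (t_i^alpha - t_{i-1}^alpha), K_alpha = D dt^(1-alpha); OU is the
#' exact discretization of the Ornstein-Uhlenbeck process with per-lapse
#' relaxation rate theta, started from stationarity; CTRW waits heavy-tailed
#' times between Gaussian jumps (piecewise-constant paths sampled on the dt
#' grid); LW performs constant-speed flights of heavy-tailed duration in
#' uniformly random directions.
#'
#' @param model one of [MODEL_KINDS].
#' @param params one-row data.frame or list with fields `N`, `D`, `alpha`
#'   (not OU), `theta` (OU only), and optionally `noise_sd` (stored in meta).
#' @param dt time lapse in seconds.
#' @param track_id identifier for the resulting trajectory.
#' @param seed optional RNG seed.
#' @return a [trajectory()] with ground truth recorded in `meta`.
#' @export
simulate_trajectory <- function(model, params, dt = 0.0154, track_id = "sim",
                                seed = NULL) {
  model <- as.character(model)
  if (!model %in% MODEL_KINDS) stop("unknown model kind: ", model)
  N <- as.integer(params$N); D <- as.numeric(params$D)
  alpha <- as.numeric(params$alpha %||% NA_real_)
  if (N < 2L) stop("N must be >= 2")
  if (!is.finite(D) || D <= 0) stop("D must be positive")
  check_alpha <- function(lo, hi)
    if (!is.finite(alpha) || alpha < lo - 1e-9 || alpha > hi + 1e-9)
      stop(sprintf("alpha = %s outside the %s range [%g, %g]", alpha, model, lo, hi))
  pos <- with_seed(seed, switch(
    model,
    fBM  = { check_alpha(0, 2); sim_fbm(N, D, alpha, dt) },
    sBM  = { check_alpha(0, 2); sim_sbm(N, D, alpha, dt) },
    OU   = {
      theta <- as.numeric(params$theta)
      if (!is.finite(theta) || theta <= 0) stop("OU needs theta > 0")
      sim_ou(N, D, theta, dt)
    },
    CTRW = { check_alpha(0, 1); sim_ctrw(N, D, alpha, dt) },
    LW   = { check_alpha(1, 2); sim_lw(N, D, alpha, dt) }
  ))
  trajectory(pos, dt = dt, track_id = track_id,
             meta = list(model = model, alpha = alpha, D = D,
                         theta = as.numeric(params$theta %||% NA_real_),
                         noise_sd = as.numeric(params$noise_sd %||% NA_real_)))
}

#' Add localisation noise to a trajectory
#'
#' Perturbs every coordinate by independent centred Gaussian noise emulating
#' the localisation uncertainty of single-molecule microscopy. The
#' noise-free positions are retained in `meta$true_positions`.
#'
#' @param t a [trajectory()].
#' @param noise_sd noise standard deviation in um (>= 0).
#' @param seed optional RNG seed.
#' @return the noisy [trajectory()].
#' @export
add_localization_noise <- function(t, noise_sd, seed = NULL) {
  stopifnot(inherits(t, "trajectory"), noise_sd >= 0)
  if (noise_sd == 0) return(t)
  n <- nrow(t$positions)
  noisy <- with_seed(seed,
    t$positions + matrix(stats::rnorm(2L * n, sd = noise_sd), n, 2L))
  out <- trajectory(noisy, t$dt, t$track_id, t$meta)
  out$meta$true_positions <- t$positions
  out$meta$noise_sd <- noise_sd
  out
}

#' Generate a labelled synthetic trajectory set
#'
#' Draws `n` trajectories whose generative models follow the mixture
#' fractions (multinomial assignment), samples each model's parameters from
#' the prior, simulates the trajectory, and adds localisation noise at the
#' per-trajectory sd drawn from the prior. Fully reproducible by seed.
#'
#' @param mixture a [mixture_spec()].
#' @param n number of trajectories.
#' @param prior a [sim_prior()].
#' @param seed optional RNG seed.
#' @param label group label.
#' @param noise add localisation noise (default TRUE).
#' @return a [trajectory_group()] with ground-truth meta on each trajectory.
#' @export
generate_dataset <- function(mixture, n, prior = sim_prior(), seed = NULL,
                             label = "sim", noise = TRUE) {
  stopifnot(inherits(mixture, "mixture_spec"), n >= 1)
  with_seed(seed, {
    models <- sample(names(mixture$fractions), n, replace = TRUE,
                     prob = mixture$fractions)
    params <- sample_prior(prior, models, n)
    trajs <- vector("list", n)
    for (i in seq_len(n)) {
      t <- simulate_trajectory(params$model[i], params[i, ], dt = prior$dt,
                               track_id = sprintf("%s_%06d", label, i))
      if (noise) t <- add_localization_noise(t, params$noise_sd[i])
      trajs[[i]] <- t
    }
    trajectory_group(trajs, label = label)
  })
}
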