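#' The five canonical random-walk models
#'
#' Closed enumeration of the generative models used for simulation-based
#' inference: fractional Brownian motion (fBM), scaled Brownian motion (sBM),
#' the Ornstein-Uhlenbeck process (OU), the continuous-time random walk
#' (CTRW) and the Levy walk (LW).
#' @export
MODEL_KINDS <- c("fBM", "sBM", "OU", "CTRW", "LW")

#' Simulation prior
#'
#' Parameter distributions from which trajectories are simulated, shared
#' across the whole analysis. Defaults: trajectory length log-uniform on
#' \[7, 25\] points (mean 14); effective diffusivity log-normal with
#' D0 = 1 um^2/s, mean log10(D/D0) = -0.5 and sd 0.5; OU relaxation rate
#' log-uniform on \[0.01, 1\] (per time lapse); localisation noise sd uniform
#' on \[0.015, 0.040\] um; time lapse 15.4 ms. The anomalous-exponent ranges
#' follow the conventions of the anomalous-diffusion challenge:
#' fBM and sBM alpha ~ U\[0.2, 1.8\], CTRW alpha ~ U\[0.2, 1\],
#' LW alpha ~ U\[1, 2\]; OU has no anomalous exponent.
#'
#' @param length_low,length_high bounds of the log-uniform length prior
#'   (points).
#' @param D0 reference diffusivity (um^2/s).
#' @param logD_mean,logD_sd mean and sd of log10(D / D0).
#' @param theta_low,theta_high bounds of the log-uniform OU relaxation-rate
#'   prior (per time lapse).
#' @param noise_sd_low,noise_sd_high bounds of the uniform localisation-noise
#'   prior (um).
#' @param dt time lapse (seconds).
#' @param alpha_ranges named list of c(low, high) anomalous-exponent ranges
#'   per model.
#' @return an object of class `"sim_prior"`.
#' @export
sim_prior <- function(length_low = 7, length_high = 25,
                      D0 = 1, logD_mean = -0.5, logD_sd = 0.5,
                      theta_low = 0.01, theta_high = 1,
                      noise_sd_low = 0.015, noise_sd_high = 0.040,
                      dt = 0.0154,
                      alpha_ranges = list(fBM = c(0.2, 1.8),
                                          sBM = c(0.2, 1.8),
                                          CTRW = c(0.2, 1.0),
                                          LW = c(1.0, 2.0))) {
  p <- list(length_low = length_low, length_high = length_high, D0 = D0,
            logD_mean = logD_mean, logD_sd = logD_sd,
            theta_low = theta_low, theta_high = theta_high,
            noise_sd_low = noise_sd_low, noise_sd_high = noise_sd_high,
            dt = dt, alpha_ranges = alpha_ranges)
  rng <- c(length_low, length_high, D0, logD_sd, theta_low, theta_high,
           noise_sd_low, noise_sd_high, dt)
  if (any(!is.finite(rng)) || any(rng <= 0))
    stop("all prior bounds must be positive and finite")
  for (pair in list(c(length_low, length_high), c(theta_low, theta_high),
                    c(noise_sd_low, noise_sd_high)))
    if (pair[1L] >= pair[2L]) stop("prior ranges need low < high")
  structure(p, class = "sim_prior")
}

#' @export
print.sim_prior <- function(x, ...) {
  cat(sprintf(paste0("<sim_prior> length ~ logU[%g, %g], log10(D/%g) ~ N(%g, %g^2),\n",
                     "  theta ~ logU[%g, %g], noise sd ~ U[%g, %g] um, dt = %g s\n"),
              x$length_low, x$length_high, x$D0, x$logD_mean, x$logD_sd,
              x$theta_low, x$theta_high, x$noise_sd_low, x$noise_sd_high, x$dt))
  invisible(x)
}

#' Sample model parameters from the prior
#'
#' @param prior a [sim_prior()].
#' @param model one of [MODEL_KINDS], or a vector of them (recycled against
#'   `n`).
#' @param n number of parameter records to draw.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @return data.frame with columns `model, N, D, alpha, theta, noise_sd`
#'   (`alpha` is `NA` for OU; `theta` is `NA` except for OU).
#' @export
sample_prior <- function(prior, model, n = 1L, seed = NULL) {
  stopifnot(inherits(prior, "sim_prior"))
  model <- rep_len(as.character(model), n)
  if (!all(model %in% MODEL_KINDS)) stop("unknown model kind")
  with_seed(seed, {
    N <- pmin(pmax(as.integer(round(exp(stats::runif(
      n, log(prior$length_low), log(prior$length_high))))),
      as.integer(prior$length_low)), as.integer(prior$length_high))
    D <- prior$D0 * 10^stats::rnorm(n, prior$logD_mean, prior$logD_sd)
    alpha <- rep(NA_real_, n)
    for (m in setdiff(unique(model), "OU")) {
      idx <- model == m
      r <- prior$alpha_ranges[[m]]
      alpha[idx] <- stats::runif(sum(idx), r[1L], r[2L])
    }
    theta <- rep(NA_real_, n)
    idx <- model == "OU"
    if (any(idx))
      theta[idx] <- exp(stats::runif(sum(idx), log(prior$theta_low),
                                     log(prior$theta_high)))
    noise_sd <- stats::runif(n, prior$noise_sd_low, prior$noise_sd_high)
    data.frame(model = model, N = N, D = D, alpha = alpha, theta = theta,
               noise_sd = noise_sd, stringsAsFactors = FALSE)
  })
}

#' Mixture specification for two-sample experiments
#'
#' Describes the model composition of a simulated trajectory set. The power
#' experiments compare a pure sBM set against a set with a fraction `nu` of
#' fBM (and 1 - nu sBM), or two fBM sets with anomalous exponents 1 - delta
#' and 1 + delta.
#'
#' @param fractions named numeric vector of model fractions (names in
#'   [MODEL_KINDS]); must sum to 1.
#' @return an object of class `"mixture_spec"`.
#' @export
mixture_spec <- function(fractions) {
  fractions <- unlist(fractions)
  if (is.null(names(fractions)) || !all(names(fractions) %in% MODEL_KINDS))
    stop("fractions must be named by model kind")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be non-negative and sum to 1")
  structure(list(fractions = fractions), class = "mixture_spec")
}
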