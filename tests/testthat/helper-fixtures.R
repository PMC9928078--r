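## Deterministic fixtures built in code.

## a simple hand-made trajectory from explicit displacements
traj_from_steps <- function(steps, dt = 0.0154, start = c(0, 0), ...) {
  pos <- rbind(start, start + apply(steps, 2L, cumsum))
  trajectory(pos, dt = dt, ...)
}

uniform_mixture <- function() {
  mixture_spec(stats::setNames(rep(1 / 5, 5), MODEL_KINDS))
}

## brute-force MMD_u^2 oracle: direct double loops over Eq-style sums
mmd_u2_bruteforce <- function(X, Y, sigma) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  m <- nrow(X); n <- nrow(Y)
  sxx <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    sxx <- sxx + k(X[i, ], X[j, ])
  syy <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    syy <- syy + k(Y[i, ], Y[j, ])
  sxy <- 0
  for (i in seq_len(m)) for (j in seq_len(n))
    sxy <- sxy + k(X[i, ], Y[j, ])
  sxx / (m * (m - 1)) + syy / (n * (n - 1)) - 2 * sxy / (m * n)
}

## offset-enumeration oracle for the causal wiring scheme
edge_index_oracle <- function(N, k = 10L) {
  src <- integer(0); dst <- integer(0)
  for (i in 2:N) {
    if (N < k) {
      s <- 1:(i - 1L)
    } else {
      gamma <- (i - 1)^(1 / (k - 1))
      offs <- floor(gamma^(0:(k - 1L)) + 1e-9)
      offs <- sort(unique(offs[offs >= 1 & offs <= i - 1]))
      s <- sort(unique(i - offs))
    }
    src <- c(src, s); dst <- c(dst, rep.int(i, length(s)))
  }
  cbind(src = src, dst = dst)
}

## a reduced-scale trained encoder + projection shared across test files;
## trained once per test run (seeded, deterministic)
trained_encoder <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- encoder_config(n_train = 4e4, epochs = 4L)
      m <- fit_encoder(config = cfg, seed = 20240601, verbose = FALSE)
      lat <- encode(m, generate_dataset(uniform_mixture(), 12000, sim_prior(),
                                        seed = 777, label = "proj"))
      m$projection <- fit_projection_2d(lat, seed = 31)
      cache <<- m
    }
    cache
  }
})
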