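# Shared fixtures, built in code.

# Small scenario-I dataset on a reduced grid: keeps unit tests fast while
# preserving the generative structure (binary patterns, one-hot loadings,
# negative binomial noise).
small_sim1 <- function(seed = 5, n_features = 40, grid_side = 12,
                       pattern = "quilt") {
  simulate_scenario1(pattern, n_features = n_features, seed = seed,
                     grid_side = grid_side)
}

# Random nonnegative factorization pieces for postprocessing fuzz tests.
random_nonneg <- function(N, J, L, seed = 1) {
  set.seed(seed)
  list(F = matrix(stats::rexp(N * L), N, L),
       W = matrix(stats::rexp(J * L), J, L))
}

# Random lower-triangular variational root with positive diagonal.
random_qsqrt <- function(M, seed = 1) {
  set.seed(seed)
  S <- matrix(stats::rnorm(M * M, sd = 0.3), M, M)
  S[upper.tri(S)] <- 0
  diag(S) <- abs(diag(S)) + 0.5
  S
}

# Brute-force scalar-loop Moran's I.
morans_i_loop <- function(z, W) {
  N <- length(z)
  zc <- z - mean(z)
  num <- 0
  for (i in 1:N) for (j in 1:N) num <- num + W[i, j] * zc[i] * zc[j]
  (N / sum(W)) * num / sum(zc^2)
}

# Brute-force scalar-loop mean Poisson deviance.
mean_poisson_deviance_loop <- function(y, mu) {
  per_obs <- numeric(nrow(y))
  for (i in seq_len(nrow(y))) {
    s <- 0
    for (j in seq_len(ncol(y))) {
      t1 <- if (y[i, j] > 0) y[i, j] * log(y[i, j] / mu[i, j]) else 0
      s <- s + 2 * (t1 - (y[i, j] - mu[i, j]))
    }
    per_obs[i] <- s
  }
  mean(per_obs)
}
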