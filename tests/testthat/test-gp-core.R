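test_that("kernel closed forms evaluate correctly and are PSD", {
  sp <- kernel_spec("matern32", amplitude = 1, lengthscale = 1)
  x0 <- matrix(0, 1, 1)
  expect_equal(kernel_matrix(x0, x0, sp)[1, 1], 1)              # r = 0 -> a^2
  x1 <- matrix(1 / sqrt(3), 1, 1)
  expect_equal(kernel_matrix(x0, x1, sp)[1, 1], 2 * exp(-1), tolerance = 1e-12)
  sp2 <- kernel_spec("eq", amplitude = 2, lengthscale = 0.5)
  expect_equal(kernel_matrix(x0, x1, sp2)[1, 1],
               4 * exp(-(1 / 3) / (2 * 0.25)), tolerance = 1e-12)
  set.seed(2)
  X <- matrix(stats::runif(40), 20, 2)
  for (fam in c("matern32", "eq")) {
    K <- kernel_matrix(X, X, kernel_spec(fam, 1.5, 0.3))
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  expect_error(kernel_spec("matern32", amplitude = -1), "positive")
})

test_that("linear mean function is affine in the coordinates", {
  X <- rbind(c(3, 4), c(0, 0))
  expect_equal(linear_mean(X, mean_function(1, c(2, -1))), c(3, 1))
  expect_equal(linear_mean(X, mean_function(0, c(0, 0))), c(0, 0))
  m1 <- linear_mean(X, mean_function(2, c(1, 1)))
  m2 <- linear_mean(X, mean_function(7, c(1, 1)))
  expect_equal(m2 - m1, rep(5, 2))
  expect_error(linear_mean(X, mean_function(0, c(1, 2, 3))), "dimension")
})

test_that("whitened prior state reproduces the GP prior at any query point", {
  set.seed(3)
  Z <- matrix(stats::runif(20), 10, 2)
  Xq <- matrix(stats::runif(12), 6, 2)
  sp <- kernel_spec("matern32", amplitude = 1.7, lengthscale = 0.4)
  mf <- mean_function(0.5, c(1, -2))
  pr <- svgp_predict(svgp_state(Z), sp, mf, Xq)
  expect_equal(pr$mean, linear_mean(Xq, mf), tolerance = 1e-9)
  expect_equal(pr$var, rep(1.7^2, 6), tolerance = 1e-6)
})

test_that("sparse predictions match a dense GP oracle when M = N", {
  set.seed(4)
  M <- 25
  Z <- matrix(stats::runif(2 * M), M, 2)
  q_mu <- stats::rnorm(M)
  S <- random_qsqrt(M, seed = 7)
  sp <- kernel_spec("matern32", amplitude = 1.3, lengthscale = 0.35)
  mf <- mean_function(-0.2, c(0.5, 0.1))
  state <- svgp_state(Z, q_mu, S, jitter = 1e-6)
  pr <- svgp_predict(state, sp, mf, Z)

  # dense oracle: q(f) = \int p(f | u) q(u) du with everything explicit
  Kzz <- kernel_matrix(Z, Z, sp) + diag(1e-6 * sp$amplitude^2, M)
  L <- t(chol(Kzz))
  u_mean <- linear_mean(Z, mf) + as.numeric(L %*% q_mu)
  Su <- L %*% S %*% t(S) %*% t(L)
  Kqz <- kernel_matrix(Z, Z, sp)
  Kinv <- solve(Kzz)
  mean_o <- linear_mean(Z, mf) + Kqz %*% Kinv %*% (u_mean - linear_mean(Z, mf))
  cov_o <- kernel_matrix(Z, Z, sp) - Kqz %*% Kinv %*% t(Kqz) +
    Kqz %*% Kinv %*% Su %*% Kinv %*% t(Kqz)
  expect_equal(pr$mean, as.numeric(mean_o), tolerance = 1e-6)
  expect_equal(pr$var, pmax(diag(cov_o), 1e-12), tolerance = 1e-6)
})

test_that("whitened KL matches its closed form and a Monte-Carlo estimate", {
  Z3 <- matrix(stats::runif(6), 3, 2)
  expect_equal(svgp_kl(svgp_state(Z3)), 0)
  st <- svgp_state(Z3, q_mu = c(1, 0, 0))
  expect_equal(svgp_kl(st), 0.5)
  # Monte-Carlo oracle on a random 3-dim state: KL(N(mu, SS') || N(0, I))
  set.seed(11)
  S <- random_qsqrt(3, seed = 5)
  mu <- c(0.4, -0.7, 1.1)
  st2 <- svgp_state(Z3, mu, S)
  n <- 2e5
  zs <- matrix(stats::rnorm(3 * n), 3, n)
  x <- mu + S %*% zs
  Sigma <- S %*% t(S)
  logq <- -0.5 * (3 * log(2 * pi) + determinant(Sigma)$modulus[1] +
                    colSums((solve(S, x - mu))^2))
  logp <- -0.5 * (3 * log(2 * pi) + colSums(x^2))
  mc <- mean(logq - logp)
  se <- stats::sd(logq - logp) / sqrt(n)
  expect_lt(abs(svgp_kl(st2) - mc), 4 * se)
  # nonnegativity on random states
  for (s in 1:20) {
    expect_gte(svgp_kl(svgp_state(Z3, stats::rnorm(3), random_qsqrt(3, s))), 0)
  }
})

test_that("predictive variance shrinks as the variational root contracts", {
  set.seed(6)
  Z <- matrix(stats::runif(16), 8, 2)
  sp <- kernel_spec("matern32", 1, 0.3)
  mf <- mean_function(0, c(0, 0))
  vs <- sapply(c(1, 0.5, 0.2, 0.05), function(d) {
    sum(svgp_predict(svgp_state(Z, q_sqrt = diag(d, 8)), sp, mf, Z)$var)
  })
  expect_true(all(diff(vs) < 0))
})

test_that("inducing-point strategies behave as documented", {
  X <- make_grid_coords(6)
  expect_equal(nrow(choose_inducing_points(X, strategy = "all")), 36)
  # duplicated coordinates collapse to unique locations
  Xdup <- X[rep(1:10, each = 5), ]
  expect_equal(nrow(choose_inducing_points(Xdup, strategy = "all")), 10)
  set.seed(1)
  Xr <- matrix(stats::rnorm(30), 15, 2)
  Zk <- choose_inducing_points(Xr, M = 15, strategy = "kmeans", seed = 2)
  expect_equal(nrow(Zk), 15)
  expect_equal(Xr[order(Xr[, 1]), ], unname(Zk[order(Zk[, 1]), ]),
               tolerance = 1e-12)
  expect_error(choose_inducing_points(Xr, M = 20, strategy = "random"), "M")
})
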