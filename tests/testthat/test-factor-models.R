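# Small fixtures reused across blocks.
fm_sim <- small_sim1(seed = 5, n_features = 40, grid_side = 12)

test_that("the intensity combines spatial and nonspatial blocks correctly", {
  # 1 obs, 2 components: w = 2, v = 3, f = 0, h = ln 2 -> lambda = 2 + 6 = 8
  lam <- rate_matrix(list(W = matrix(2, 1, 1), V = matrix(3, 1, 1)),
                     F_draw = matrix(0, 1, 1), H_draw = matrix(log(2), 1, 1))
  expect_equal(lam[1, 1], 8)
  # special cases: T = L reduces to the all-spatial form, T = 0 to the
  # all-nonspatial form, and the hybrid is their sum
  set.seed(1)
  F <- matrix(stats::rnorm(12), 4, 3); W <- matrix(stats::rexp(15), 5, 3)
  H <- matrix(stats::rnorm(8), 4, 2); V <- matrix(stats::rexp(10), 5, 2)
  expect_equal(rate_matrix(list(W = W), F_draw = F), exp(F) %*% t(W))
  expect_equal(rate_matrix(list(V = V), H_draw = H), exp(H) %*% t(V))
  expect_equal(rate_matrix(list(W = W, V = V), F, H),
               exp(F) %*% t(W) + exp(H) %*% t(V))
  # size factors scale the intensity linearly
  nu <- c(1, 2, 3, 4)
  expect_equal(rate_matrix(list(W = W), F_draw = F, nu = nu),
               nu * (exp(F) %*% t(W)))
  expect_error(rate_matrix(list(W = -W), F_draw = F), "nonnegative")
})

test_that("log-likelihoods match closed forms and the NB Poisson limit", {
  expect_equal(log_likelihood(0, 1, "poisson"), -1)
  expect_equal(log_likelihood(2, 2, "poisson"), log(2) - 2)
  expect_equal(log_likelihood(1, 2, "gaussian", sigma2 = 4),
               stats::dnorm(1, 2, 2, log = TRUE))
  y <- matrix(c(0, 3, 7, 1), 2, 2)
  mu <- matrix(c(0.5, 2, 6, 1.5), 2, 2)
  expect_equal(log_likelihood(y, mu, "negative_binomial", theta = 1e8),
               log_likelihood(y, mu, "poisson"), tolerance = 1e-4)
  expect_error(log_likelihood(1, -1, "poisson"), "positive")
})

test_that("the ELBO estimate matches a from-scratch reconstruction (PNMF)", {
  set.seed(30)
  Y <- matrix(stats::rpois(18, 4) + 1, 6, 3)
  d <- count_dataset(Y, make_grid_coords(3)[1:6, ], nu = c(1, 2, 1, 1, 0.5, 1))
  model <- new_factor_model(d, "pnmf", L = 2, seed = 1)
  cfg <- fit_config(n_samples_elbo = 2)
  got <- elbo_estimate(model, cfg, seed = 77)
  # independent reconstruction from the model definition
  P <- model$params
  set.seed(77)
  ll <- 0
  for (s in 1:2) {
    EpsH <- matrix(stats::rnorm(12), 6, 2)
    Hd <- P$Hm + exp(P$Hls) * EpsH
    Lam <- exp(Hd) %*% t(exp(P$Vu))
    ll <- ll + sum(stats::dpois(Y, d$nu * Lam, log = TRUE))
  }
  kl <- 0
  for (l in 1:2) for (i in 1:6) {
    s2 <- exp(2 * P$log_s[l]); hs2 <- exp(2 * P$Hls[i, l])
    kl <- kl + P$log_s[l] - P$Hls[i, l] +
      (hs2 + (P$Hm[i, l] - P$m[l])^2) / (2 * s2) - 0.5
  }
  expect_equal(got, ll / 2 - kl, tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences for every family", {
  eng <- function(m, seed = 99) {
    set.seed(seed)
    nsfkit:::.engine(m, seq_len(m$cache$N), 2, want_grads = TRUE)
  }
  check_grads <- function(model, n_per = 4, tol = 1e-4) {
    force(model)   # construct before eng() seeds the sampling RNG
    base <- eng(model)
    h <- 1e-5
    set.seed(1)
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      if (length(p) == 0) next
      for (i in sample(seq_along(p), min(n_per, length(p)))) {
        if (nm == "Qs") {   # skip structurally unused upper-triangle slots
          M <- dim(p)[1]; pos <- (i - 1) %% (M * M)
          if (pos %/% M + 1 > pos %% M + 1) next
        }
        mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
        mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
        fd <- (eng(mp)$elbo - eng(mm)$elbo) / (2 * h)
        an <- base$grads[[nm]][i]
        expect_lt(abs(fd - an) / max(1, abs(fd), abs(an)), tol)
      }
    }
  }
  d <- fm_sim$data
  check_grads(new_factor_model(d, "nsfh", L = 4, T = 2,
                               likelihood = "negative_binomial",
                               M = 10, ip_strategy = "kmeans", seed = 2))
  check_grads(new_factor_model(d, "nsf", L = 3, M = 8,
                               ip_strategy = "kmeans", seed = 2))
  check_grads(new_factor_model(d, "rsf", L = 3, M = 8,
                               ip_strategy = "kmeans", seed = 2))
  check_grads(new_factor_model(d, "fa", L = 3, seed = 2))
  check_grads(new_factor_model(d, "pnmf", L = 3, seed = 2))
})

test_that("nonspatial families ignore observation order; spatial ones do not", {
  set.seed(40)
  Y <- matrix(stats::rpois(60, 5) + 1, 12, 5)
  X <- make_grid_coords(4)[1:12, ]
  d <- count_dataset(Y, X)
  cfg <- fit_config(n_samples_elbo = 1)
  pn <- new_factor_model(d, "pnmf", L = 2, seed = 1)
  pn$params$Hls[] <- log(1e-8)   # near-deterministic draws
  perm <- sample(12)
  pn2 <- pn
  pn2$cache$Yfit <- pn$cache$Yfit[perm, ]
  pn2$cache$Y <- pn$cache$Y[perm, ]
  pn2$cache$nu <- pn$cache$nu[perm]
  pn2$params$Hm <- pn$params$Hm[perm, ]
  expect_equal(elbo_estimate(pn, cfg, seed = 5),
               elbo_estimate(pn2, cfg, seed = 5), tolerance = 1e-6)
  # NSF: permuting the outcomes without the coordinates changes the ELBO
  ns <- new_factor_model(d, "nsf", L = 2, M = 6, ip_strategy = "kmeans",
                         seed = 1)
  ns$params$Qs[] <- ns$params$Qs * 0
  diag_idx <- cbind(rep(1:6, 2), rep(1:6, 2), rep(1:2, each = 6))
  ns$params$Qs[diag_idx] <- log(1e-8)
  ns2 <- ns
  ns2$cache$Yfit <- ns$cache$Yfit[perm, ]
  expect_gt(abs(elbo_estimate(ns, cfg, seed = 5) -
                  elbo_estimate(ns2, cfg, seed = 5)), 1e-3)
})

test_that("minibatch ELBO estimates are unbiased for the full-batch ELBO", {
  set.seed(50)
  Y <- matrix(stats::rpois(100, 6) + 1, 20, 5)
  d <- count_dataset(Y, make_grid_coords(5)[1:20, ])
  model <- new_factor_model(d, "pnmf", L = 2, seed = 1)
  full <- sapply(1:200, function(s)
    elbo_estimate(model, fit_config(n_samples_elbo = 1), seed = s))
  half <- sapply(1:200, function(s)
    elbo_estimate(model, fit_config(n_samples_elbo = 1, batch_size = 10),
                  seed = 1000 + s))
  se <- sqrt(stats::var(full) / 200 + stats::var(half) / 200)
  expect_lt(abs(mean(full) - mean(half)), 3 * se)
})

test_that("predicted factors use the correct lognormal mean of e^f", {
  set.seed(60)
  Z <- matrix(stats::runif(10), 5, 2)
  sp <- kernel_spec("matern32", 1.2, 0.3)
  st <- svgp_state(Z, q_mu = stats::rnorm(5), q_sqrt = random_qsqrt(5, 3))
  pr <- svgp_predict(st, sp, mean_function(0.3, c(0.5, -0.2)), Z[1:2, ])
  for (i in 1:2) {
    draws <- exp(stats::rnorm(2e6, pr$mean[i], sqrt(pr$var[i])))
    expect_equal(exp(pr$mean[i] + pr$var[i] / 2), mean(draws),
                 tolerance = 2e-3)
  }
})

test_that("predictions respect zeroed loadings and interpolate the fit", {
  d <- fm_sim$data
  model <- new_factor_model(d, "nsf", L = 2, M = 12, ip_strategy = "kmeans",
                            seed = 3)
  pred <- predict_mean(model, d$X[1:10, ])
  model0 <- model
  model0$params$Wu[, 2] <- -60   # effectively zero loading column
  pred0 <- predict_mean(model0, d$X[1:10, ])
  # component 2 contributes nothing: prediction equals component-1 part
  sm <- nsfkit:::.spatial_moments(model, 1:10)
  f1 <- exp(sm$mean[, 1] + sm$var[, 1] / 2)
  manual <- f1 %*% t(exp(model$params$Wu[, 1, drop = FALSE]))
  expect_equal(pred0, pmax(manual, 1e-10), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(pred, pred0)))
})

test_that("fitting reduces the objective and is reproducible", {
  set.seed(70)
  F0 <- matrix(stats::rnorm(40), 20, 2)
  W0 <- matrix(stats::rnorm(16), 8, 2)
  Y <- round(exp(F0 %*% t(W0) / 2) * 5)
  d <- count_dataset(Y + 1, make_grid_coords(5)[1:20, ])
  cfg <- fit_config(max_iter = 120, seed = 2)
  r1 <- nsf_fit(d, "fa", L = 2, config = cfg)
  expect_lt(mean(utils::tail(r1$trace$objective, 10)),
            mean(utils::head(r1$trace$objective, 10)))
  r2 <- nsf_fit(d, "fa", L = 2, config = cfg)
  expect_identical(r1$trace, r2$trace)
  # nonnegative loadings stay nonnegative throughout optimization
  r3 <- nsf_fit(d, "pnmf", L = 2, config = fit_config(max_iter = 40, seed = 1))
  ld <- model_loadings(r3$model)
  expect_true(all(ld$V >= 0))
})
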