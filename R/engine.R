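# Monte-Carlo ELBO and analytic reparameterization gradients.
#
# The ELBO is estimated by sampling each factor's variational marginal
# (local reparameterization: f_il = mean_il + sd_il * eps with eps ~ N(0,1);
# the likelihood factorizes over entries so only marginals matter) and
# averaging the log-likelihood, minus the whitened KL of each spatial
# component and the mean-field Gaussian KL of each nonspatial factor value.
# All gradients are derived by hand; `.engine` is validated against finite
# differences in the test suite using common random numbers.

.engine <- function(model, idx, n_samples, want_grads = TRUE) {
  P <- model$params; ca <- model$cache
  Tn <- model$T; Lns <- model$Lns
  n <- length(idx); scale <- ca$N / n
  Yb <- ca$Yfit[idx, , drop = FALSE]
  nu_b <- ca$nu[idx]
  Xb <- ca$Xs[idx, , drop = FALSE]
  J <- ca$J

  sm <- .spatial_moments(model, idx)
  sd_F <- sqrt(pmax(sm$var, 1e-12))
  Hm_b <- P$Hm[idx, , drop = FALSE]
  Hs_b <- exp(P$Hls[idx, , drop = FALSE])

  if (model$nonneg) {
    W <- exp(P$Wu); V <- exp(P$Vu)
  } else {
    W <- P$Wu; V <- P$Vu
  }
  theta <- if (model$likelihood == "negative_binomial") exp(P$log_theta) else NULL
  thetaM <- if (!is.null(theta)) matrix(theta, n, J, byrow = TRUE) else NULL
  sigma2 <- if (model$likelihood == "gaussian") exp(P$log_sigma2) else NULL

  ll_sum <- 0
  gW_a <- matrix(0, J, Tn); gV_a <- matrix(0, J, Lns)
  gF_a <- matrix(0, n, Tn); gFsd_a <- matrix(0, n, Tn)
  gH_a <- matrix(0, n, Lns); gHsd_a <- matrix(0, n, Lns)
  gth_a <- if (!is.null(theta)) numeric(J) else NULL
  gsig_a <- if (!is.null(sigma2)) numeric(J) else NULL

  for (s in seq_len(n_samples)) {
    EpsF <- matrix(stats::rnorm(n * Tn), n, Tn)
    EpsH <- matrix(stats::rnorm(n * Lns), n, Lns)
    Fd <- sm$mean + sd_F * EpsF
    Hd <- Hm_b + Hs_b * EpsH
    if (model$nonneg) {
      EF <- exp(Fd); EH <- exp(Hd)
      Lam <- pmax(EF %*% t(W) + EH %*% t(V), 1e-10)
      if (model$likelihood == "poisson") {
        rate <- nu_b * Lam
        ll_sum <- ll_sum + sum(stats::dpois(Yb, rate, log = TRUE))
        Gl <- Yb / Lam - nu_b
      } else {
        mu <- nu_b * Lam
        ll_sum <- ll_sum + sum(stats::dnbinom(Yb, mu = mu, size = thetaM, log = TRUE))
        Gmu <- Yb / mu - (Yb + thetaM) / (thetaM + mu)
        Gl <- nu_b * Gmu
        if (want_grads) {
          dth <- digamma(Yb + thetaM) - digamma(thetaM) +
            log(thetaM / (thetaM + mu)) + 1 - (thetaM + Yb) / (thetaM + mu)
          gth_a <- gth_a + colSums(dth) * theta
        }
      }
      if (want_grads) {
        if (Tn > 0) {
          gW_a <- gW_a + crossprod(Gl, EF)
          gFs <- (Gl %*% W) * EF
          gF_a <- gF_a + gFs
          gFsd_a <- gFsd_a + gFs * EpsF
        }
        if (Lns > 0) {
          gV_a <- gV_a + crossprod(Gl, EH)
          gHs <- (Gl %*% V) * EH
          gH_a <- gH_a + gHs
          gHsd_a <- gHsd_a + gHs * EpsH
        }
      }
    } else {
      Mu <- Fd %*% t(W) + Hd %*% t(V)
      resid <- Yb - Mu
      sig2M <- matrix(sigma2, n, J, byrow = TRUE)
      ll_sum <- ll_sum + sum(stats::dnorm(Yb, Mu, sqrt(sig2M), log = TRUE))
      if (want_grads) {
        Gl <- resid / sig2M
        gsig_a <- gsig_a + colSums(-0.5 + resid^2 / (2 * sig2M))
        if (Tn > 0) {
          gW_a <- gW_a + crossprod(Gl, Fd)
          gFs <- Gl %*% W
          gF_a <- gF_a + gFs
          gFsd_a <- gFsd_a + gFs * EpsF
        }
        if (Lns > 0) {
          gV_a <- gV_a + crossprod(Gl, Hd)
          gHs <- Gl %*% V
          gH_a <- gH_a + gHs
          gHsd_a <- gHsd_a + gHs * EpsH
        }
      }
    }
  }
  ll_bar <- ll_sum / n_samples

  # KL penalties
  kl_sp <- 0
  if (Tn > 0) {
    for (l in seq_len(Tn)) {
      S <- .qs_mat(P$Qs[, , l])
      kl_sp <- kl_sp + 0.5 * (sum(P$Qmu[, l]^2) + sum(S^2) - ca$M -
                                2 * sum(diag(P$Qs[, , l])))
    }
  }
  kl_ns <- 0
  if (Lns > 0) {
    s2 <- matrix(exp(2 * P$log_s), n, Lns, byrow = TRUE)
    ml <- matrix(P$m, n, Lns, byrow = TRUE)
    klm <- matrix(P$log_s, n, Lns, byrow = TRUE) - P$Hls[idx, , drop = FALSE] +
      (Hs_b^2 + (Hm_b - ml)^2) / (2 * s2) - 0.5
    kl_ns <- sum(klm)
  }
  elbo <- scale * ll_bar - kl_sp - scale * kl_ns

  if (!want_grads) return(list(elbo = elbo, grads = NULL))

  g <- list()
  if (model$nonneg) {
    g$Wu <- scale * (gW_a / n_samples) * W
    g$Vu <- scale * (gV_a / n_samples) * V
  } else {
    g$Wu <- scale * gW_a / n_samples
    g$Vu <- scale * gV_a / n_samples
  }

  g$log_a <- numeric(Tn); g$beta0 <- numeric(Tn)
  g$beta1 <- matrix(0, ca$D, Tn)
  g$Qmu <- matrix(0, ca$M, Tn); g$Qs <- array(0, c(ca$M, ca$M, Tn))
  if (Tn > 0) {
    A <- ca$Atilde[, idx, drop = FALSE]
    a <- exp(P$log_a)
    for (l in seq_len(Tn)) {
      gl <- scale * gF_a[, l] / n_samples
      gsd <- scale * gFsd_a[, l] / n_samples
      g$beta0[l] <- sum(gl)
      g$beta1[, l] <- as.numeric(crossprod(Xb, gl))
      g$Qmu[, l] <- a[l] * as.numeric(A %*% gl) - P$Qmu[, l]
      g$log_a[l] <- a[l] * sum(gl * sm$Aq[, l]) + sum(gsd * sd_F[, l])
      S <- .qs_mat(P$Qs[, , l])
      wv <- a[l]^2 * gsd / sd_F[, l]
      ADA <- tcrossprod(sweep(A, 2, wv, "*"), A)
      GS <- ADA %*% S - S
      diag(GS) <- diag(GS) + 1 / diag(S)
      GS[upper.tri(GS)] <- 0
      diag(GS) <- diag(GS) * diag(S)    # chain rule: diag stored on log scale
      g$Qs[, , l] <- GS
    }
  }

  g$Hm <- matrix(0, ca$N, Lns); g$Hls <- matrix(0, ca$N, Lns)
  g$m <- numeric(Lns); g$log_s <- numeric(Lns)
  if (Lns > 0) {
    s2 <- matrix(exp(2 * P$log_s), n, Lns, byrow = TRUE)
    ml <- matrix(P$m, n, Lns, byrow = TRUE)
    dev <- Hm_b - ml
    g$Hm[idx, ] <- scale * (gH_a / n_samples - dev / s2)
    g$Hls[idx, ] <- scale * ((gHsd_a / n_samples) * Hs_b + 1 - Hs_b^2 / s2)
    g$m <- scale * colSums(dev / s2)
    g$log_s <- scale * colSums((Hs_b^2 + dev^2) / s2 - 1)
  }
  if (!is.null(theta)) g$log_theta <- scale * gth_a / n_samples
  if (!is.null(sigma2)) g$log_sigma2 <- scale * gsig_a / n_samples

  list(elbo = elbo, grads = g)
}

#' Monte-Carlo estimate of the evidence lower bound
#'
#' Draws reparameterized samples of the factors from their variational
#' marginals, averages the log-likelihood over the samples and, when a
#' minibatch is used, rescales it (and the per-observation KL terms) to
#' the full data size, then subtracts the KL penalties. The estimate is
#' unbiased for the ELBO and reproducible given `seed`.
#'
#' @param model a `factor_model`.
#' @param config a [fit_config()]; `n_samples_elbo` and `batch_size` are
#'   used.
#' @param seed optional seed; when `NULL`, the current RNG stream is used.
#' @return scalar ELBO estimate.
#' @export
elbo_estimate <- function(model, config = fit_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- model$cache$N
  bs <- if (is.null(config$batch_size)) N else min(config$batch_size, N)
  idx <- if (bs < N) sample.int(N, bs) else seq_len(N)
  .engine(model, idx, config$n_samples_elbo, want_grads = FALSE)$elbo
}

# One Adam ascent step over a named list of numeric arrays.
.adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (length(gr) == 0) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    params[[nm]] <- params[[nm]] +
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Fit a factor model by stochastic gradient ascent on the ELBO
#'
#' Runs Adam on the Monte-Carlo ELBO with analytic reparameterization
#' gradients, recording the raw objective (negative ELBO estimate) at
#' every iteration. Optimization stops when the smoothed-trace detector
#' ([check_convergence()]) fires or `max_iter` is reached. If the
#' objective becomes non-finite the last finite parameter state is
#' restored and fitting aborts with a warning.
#'
#' @param model an initialized `factor_model` (see [new_factor_model()]).
#' @param config a [fit_config()].
#' @return list with `model` (fitted), `trace` (data frame with columns
#'   `iteration`, `objective`), and `converged_at` (iteration, or `NA` if
#'   `max_iter` was reached first).
#' @export
fit_model <- function(model, config = fit_config()) {
  N <- model$cache$N
  bs <- if (is.null(config$batch_size)) {
    if (N <= 3000) N else 1000L
  } else {
    min(config$batch_size, N)
  }
  set.seed(config$seed)
  state <- list(
    t = 0,
    m = lapply(model$params, function(p) p * 0),
    v = lapply(model$params, function(p) p * 0)
  )
  trace <- numeric(config$max_iter)
  converged_at <- NA_integer_
  n_done <- 0
  for (it in seq_len(config$max_iter)) {
    idx <- if (bs < N) sample.int(N, bs) else seq_len(N)
    eng <- .engine(model, idx, config$n_samples_elbo, want_grads = TRUE)
    if (!is.finite(eng$elbo)) {
      warning("non-finite objective at iteration ", it,
              "; stopping at the last finite state")
      break
    }
    trace[it] <- -eng$elbo
    n_done <- it
    upd <- .adam_step(model$params, eng$grads, state, config$learning_rate)
    model$params <- upd$params
    state <- upd$state
    if (it >= config$conv_start &&
        (it - config$conv_start) %% config$conv_stride == 0) {
      conv <- check_convergence(trace[seq_len(it)], start = config$conv_start,
                                window = config$conv_window,
                                stride = config$conv_stride,
                                tol = config$conv_tol)
      if (!is.null(conv)) {
        converged_at <- conv
        break
      }
    }
  }
  list(
    model = model,
    trace = data.frame(iteration = seq_len(n_done),
                       objective = trace[seq_len(n_done)]),
    converged_at = converged_at
  )
}

#' One-call constructor + fit
#'
#' Convenience wrapper: builds an initialized model with
#' [new_factor_model()] and fits it with [fit_model()].
#'
#' @inheritParams new_factor_model
#' @param config a [fit_config()].
#' @return the [fit_model()] result.
#' @export
nsf_fit <- function(data, family, L, T = NULL, likelihood = NULL,
                    kernel = "matern32", M = NULL, ip_strategy = "all",
                    lengthscale = 0.1, seed = 1, config = fit_config()) {
  model <- new_factor_model(data, family = family, L = L, T = T,
                            likelihood = likelihood, kernel = kernel, M = M,
                            ip_strategy = ip_strategy,
                            lengthscale = lengthscale, seed = seed)
  fit_model(model, config = config)
}
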