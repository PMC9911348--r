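#' Construct an initialized spatial factor model
#'
#' Defines one of five generative models for multivariate (spatial) data
#' and initializes its parameters from the data:
#'
#' * `"fa"`: factor analysis; Gaussian likelihood, real-valued nonspatial
#'   factors (`T = 0`).
#' * `"pnmf"`: probabilistic NMF; count likelihood
#'   `y_ij ~ Poi(nu_i sum_l v_jl e^{h_il})` with nonspatial Gaussian
#'   factors (`T = 0`).
#' * `"rsf"`: real-valued spatial factorization; Gaussian likelihood with a
#'   GP prior on every factor (`T = L`).
#' * `"nsf"`: nonnegative spatial factorization;
#'   `y_ij ~ Poi(nu_i sum_l w_jl e^{f_il})` with GP priors on all factors
#'   (`T = L`).
#' * `"nsfh"`: the hybrid, `0 < T < L`:
#'   `lambda_ij = sum_{l<=T} w_jl e^{f_il} + sum_{l>T} v_jl e^{h_il}`.
#'
#' Spatial factors carry sparse variational GP posteriors with inducing
#' points (whitened parameterization), a linear mean function of the
#' coordinates, and a Matern-3/2 (or EQ) kernel with per-component
#' amplitude. Nonnegative loadings are parameterized as exponentials of
#' unconstrained reals. Nonnegative models are initialized by NMF
#' ([init_nonneg()]), real-valued models by truncated SVD ([init_real()]);
#' NSFH components are ordered by decreasing Moran's I with the first `T`
#' assigned to the spatial block ([sort_components_by_moran()]).
#'
#' @param data a [count_dataset()]. If `train_mask` is set, only training
#'   rows are used for initialization and fitting.
#' @param family one of `"fa"`, `"pnmf"`, `"rsf"`, `"nsf"`, `"nsfh"`.
#' @param L total number of components.
#' @param T number of spatial components; fixed by the family except for
#'   `"nsfh"` (default `round(L / 2)`).
#' @param likelihood `"poisson"` (default) or `"negative_binomial"` for the
#'   nonnegative families; `"gaussian"` (forced) for `"fa"` and `"rsf"`.
#' @param kernel `"matern32"` or `"eq"`.
#' @param M number of inducing points (for the kmeans/random strategies).
#' @param ip_strategy inducing-point strategy; see
#'   [choose_inducing_points()].
#' @param lengthscale kernel lengthscale on the rescaled (unit bounding
#'   box) coordinates; fixed during optimization. Default 0.1.
#' @param seed integer seed for the initialization.
#' @return object of class `factor_model`.
#' @export
new_factor_model <- function(data, family = c("nsf", "nsfh", "pnmf", "rsf", "fa"),
                             L, T = NULL, likelihood = NULL,
                             kernel = c("matern32", "eq"), M = NULL,
                             ip_strategy = c("all", "kmeans", "random"),
                             lengthscale = 0.1, seed = 1) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  ip_strategy <- match.arg(ip_strategy)
  stopifnot(inherits(data, "count_dataset"), L >= 1)

  nonneg <- family %in% c("pnmf", "nsf", "nsfh")
  T <- switch(family,
    fa = 0L, pnmf = 0L, rsf = as.integer(L), nsf = as.integer(L),
    nsfh = if (is.null(T)) as.integer(round(L / 2)) else as.integer(T)
  )
  if (family == "nsfh" && (T <= 0 || T >= L)) {
    stop("nsfh requires 0 < T < L; use nsf or pnmf for the limiting cases")
  }
  if (nonneg) {
    if (is.null(likelihood)) likelihood <- "poisson"
    likelihood <- match.arg(likelihood, c("poisson", "negative_binomial"))
  } else {
    likelihood <- "gaussian"
  }
  Lns <- L - T

  tr <- if (is.null(data$train_mask)) seq_len(nrow(data$Y)) else which(data$train_mask)
  Y <- as.matrix(data$Y[tr, , drop = FALSE])
  X <- data$X[tr, , drop = FALSE]
  nu <- data$nu[tr]
  N <- nrow(Y); J <- ncol(Y); D <- ncol(X)
  if (L > min(N, J)) stop("L must not exceed min(N, J)")

  Xs <- rescale_coords(X)
  transform <- attr(Xs, "transform")

  # --- initialization ------------------------------------------------------
  centering_means <- NULL; median_total <- NULL; Ytilde <- NULL
  if (nonneg) {
    ini <- init_nonneg(Y, L, seed = seed, nu = nu)
    if (family == "nsfh") {
      srt <- sort_components_by_moran(ini$F, ini$W, Xs, T)
      ini <- list(F = srt$F, W = srt$W)
    }
    floor_rel <- function(x) pmax(x, 1e-4 * max(x, 1e-8))
    targets <- log(apply(ini$F, 2, floor_rel))
    W0 <- log(apply(ini$W, 2, floor_rel))
  } else {
    nd <- lognormalize_center(Y)
    Ytilde <- nd$Y_tilde
    centering_means <- nd$centering_means
    median_total <- nd$median_total
    ini <- init_real(Ytilde, L)
    targets <- ini$F
    W0 <- ini$W
  }

  # --- GP precomputations (unit amplitude; amplitude enters as a scalar) ---
  jitter <- 1e-6
  Z <- NULL; Ltri <- NULL; Atilde <- NULL; ctilde <- NULL; Mi <- 0L
  if (T > 0) {
    Z <- choose_inducing_points(Xs, M = M, strategy = ip_strategy, seed = seed)
    Mi <- nrow(Z)
    unit <- kernel_spec(kernel, amplitude = 1, lengthscale = lengthscale)
    Kzz <- kernel_matrix(Z, Z, unit)
    Ltri <- .chol_jitter(Kzz, scale = 1, ladder = c(jitter, 1e-4, 1e-2))
    Atilde <- forwardsolve(Ltri, kernel_matrix(Z, Xs, unit))
    ctilde <- pmax(1 - colSums(Atilde^2), 1e-10)
  }

  params <- list(
    Wu = matrix(0, J, 0), Vu = matrix(0, J, 0),
    log_a = numeric(T), beta0 = numeric(T), beta1 = matrix(0, D, T),
    Qmu = matrix(0, Mi, T), Qs = array(0, c(Mi, Mi, T)),
    Hm = matrix(0, N, Lns), Hls = matrix(log(0.1), N, Lns),
    m = numeric(Lns), log_s = numeric(Lns)
  )
  if (T > 0) {
    params$Wu <- W0[, seq_len(T), drop = FALSE]
    ridge_A <- tcrossprod(Atilde)
    diag(ridge_A) <- diag(ridge_A) + 1e-2 * mean(diag(ridge_A)) + 1e-8
    for (l in seq_len(T)) {
      t_l <- targets[, l]
      cf <- stats::lm.fit(cbind(1, Xs), t_l)$coefficients
      cf[!is.finite(cf)] <- 0
      params$beta0[l] <- cf[1]
      params$beta1[, l] <- cf[-1]
      resid <- t_l - cf[1] - as.numeric(Xs %*% cf[-1])
      a0 <- min(max(stats::sd(resid), 0.1), 10)
      params$log_a[l] <- log(a0)
      params$Qmu[, l] <- solve(ridge_A, Atilde %*% resid) / a0
      diag(params$Qs[, , l]) <- log(0.1)
    }
  }
  if (Lns > 0) {
    params$Vu <- W0[, T + seq_len(Lns), drop = FALSE]
    params$Hm <- targets[, T + seq_len(Lns), drop = FALSE]
    params$m <- colMeans(params$Hm)
    params$log_s <- log(pmax(apply(params$Hm, 2, stats::sd), 0.1))
  }
  if (likelihood == "negative_binomial") {
    params$log_theta <- rep(log(10), J)
  }
  if (likelihood == "gaussian") {
    W_init <- cbind(params$Wu, params$Vu)
    F_init <- targets
    resid2 <- (Ytilde - F_init %*% t(W_init))^2
    params$log_sigma2 <- log(pmax(colMeans(resid2), 1e-4))
  }

  structure(
    list(
      family = family, L = as.integer(L), T = T, Lns = Lns,
      likelihood = likelihood, nonneg = nonneg,
      kernel = kernel, lengthscale = lengthscale, jitter = jitter,
      params = params,
      cache = list(
        Y = Y, Yfit = if (nonneg) Y else Ytilde, nu = nu, Xs = Xs,
        transform = transform, Z = Z, Ltri = Ltri, Atilde = Atilde,
        ctilde = ctilde, N = N, J = J, M = Mi, D = D,
        centering_means = centering_means, median_total = median_total,
        feature_ids = data$feature_ids, train_idx = tr
      )
    ),
    class = "factor_model"
  )
}

#' @method print factor_model
#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %s: L = %d (T = %d spatial), likelihood = %s\n",
              toupper(x$family), x$L, x$T, x$likelihood))
  cat(sprintf("  N = %d training obs, J = %d features", x$cache$N, x$cache$J))
  if (x$T > 0) cat(sprintf(", M = %d inducing points (%s kernel)",
                           x$cache$M, x$kernel))
  cat("\n")
  invisible(x)
}

# Lower-triangular variational root from raw storage (diag on log scale).
.qs_mat <- function(raw) {
  S <- raw
  S[upper.tri(S)] <- 0
  diag(S) <- exp(diag(raw))
  S
}

#' Loadings of a factor model on the natural scale
#'
#' @param model a `factor_model`.
#' @return list with `W` (J x T spatial) and `V` (J x (L-T) nonspatial)
#'   loadings; exponentiated for the nonnegative families.
#' @export
model_loadings <- function(model) {
  if (model$nonneg) {
    list(W = exp(model$params$Wu), V = exp(model$params$Vu))
  } else {
    list(W = model$params$Wu, V = model$params$Vu)
  }
}

#' Poisson intensity of a nonnegative factor model for given factor draws
#'
#' `Lambda_ij = nu_i (sum_{l<=T} w_jl e^{f_il} + sum_{l>T} v_jl e^{h_il})`.
#' With `T = L` this is the NSF intensity, with `T = 0` the PNMF
#' intensity.
#'
#' @param model a nonnegative `factor_model` (supplies W and V), or a plain
#'   list with elements `W` (J x T) and/or `V` (J x (L-T)) nonnegative
#'   loading blocks.
#' @param F_draw N x T real matrix of spatial factor draws (`NULL` when
#'   T = 0).
#' @param H_draw N x (L-T) real matrix of nonspatial factor draws (`NULL`
#'   when T = L).
#' @param nu length-N size factors (default 1).
#' @return N x J positive intensity matrix.
#' @export
rate_matrix <- function(model, F_draw = NULL, H_draw = NULL, nu = 1) {
  if (inherits(model, "factor_model")) {
    if (!model$nonneg) stop("rate_matrix is defined for the nonnegative families")
    ld <- model_loadings(model)
  } else {
    ld <- list(W = model$W, V = model$V)
  }
  W <- if (is.null(ld$W)) matrix(0, 0, 0) else as.matrix(ld$W)
  V <- if (is.null(ld$V)) matrix(0, 0, 0) else as.matrix(ld$V)
  if ((length(W) && min(W) < 0) || (length(V) && min(V) < 0)) {
    stop("loadings must be nonnegative")
  }
  n <- if (!is.null(F_draw)) nrow(F_draw) else nrow(H_draw)
  J <- max(nrow(W), nrow(V))
  Lam <- matrix(0, n, J)
  if (ncol(W) > 0) {
    if (is.null(F_draw) || ncol(F_draw) != ncol(W)) stop("F_draw must be N x T")
    Lam <- Lam + exp(F_draw) %*% t(W)
  }
  if (ncol(V) > 0) {
    if (is.null(H_draw) || ncol(H_draw) != ncol(V)) stop("H_draw must be N x (L-T)")
    Lam <- Lam + exp(H_draw) %*% t(V)
  }
  nu * Lam
}

#' Per-entry log-likelihood under the model families
#'
#' @param y counts (Poisson / negative binomial) or normalized values
#'   (Gaussian).
#' @param mean predicted mean, same shape as `y`.
#' @param likelihood `"poisson"`, `"negative_binomial"` or `"gaussian"`.
#' @param theta negative binomial shape (scalar, length-J vector, or
#'   matrix).
#' @param sigma2 Gaussian variance (scalar, length-J vector, or matrix).
#' @return array of per-entry log-densities, same shape as `y`.
#' @export
log_likelihood <- function(y, mean, likelihood = c("poisson", "negative_binomial", "gaussian"),
                           theta = NULL, sigma2 = NULL) {
  likelihood <- match.arg(likelihood)
  expand <- function(par, nm) {
    if (is.null(par)) stop(nm, " is required for this likelihood")
    if (is.matrix(y) && !is.matrix(par) && length(par) == ncol(y)) {
      par <- matrix(par, nrow(y), ncol(y), byrow = TRUE)
    }
    par
  }
  if (likelihood != "gaussian" && any(mean <= 0)) {
    stop("count likelihoods require strictly positive means")
  }
  out <- switch(likelihood,
    poisson = stats::dpois(y, lambda = mean, log = TRUE),
    negative_binomial = stats::dnbinom(y, mu = mean,
                                       size = expand(theta, "theta"), log = TRUE),
    gaussian = stats::dnorm(y, mean = mean,
                            sd = sqrt(expand(sigma2, "sigma2")), log = TRUE)
  )
  if (is.matrix(y)) out <- matrix(out, nrow(y), ncol(y))
  out
}

# Variational moments of the spatial factors at the cached training inputs
# (uses the precomputed whitened cross-covariances; subset by idx).
.spatial_moments <- function(model, idx) {
  P <- model$params; ca <- model$cache
  n <- length(idx); Tn <- model$T
  mean_F <- matrix(0, n, Tn); var_F <- matrix(0, n, Tn)
  Aq <- matrix(0, n, Tn)
  if (Tn == 0) return(list(mean = mean_F, var = var_F, Aq = Aq))
  A <- ca$Atilde[, idx, drop = FALSE]
  Xb <- ca$Xs[idx, , drop = FALSE]
  a <- exp(P$log_a)
  for (l in seq_len(Tn)) {
    S <- .qs_mat(P$Qs[, , l])
    Aq[, l] <- as.numeric(crossprod(A, P$Qmu[, l]))
    mean_F[, l] <- P$beta0[l] + as.numeric(Xb %*% P$beta1[, l]) + a[l] * Aq[, l]
    SA <- crossprod(S, A)
    var_F[, l] <- a[l]^2 * (ca$ctilde[idx] + colSums(SA^2))
  }
  list(mean = mean_F, var = var_F, Aq = Aq)
}

#' Point estimates of factors and loadings of a fitted model
#'
#' Returns the variational posterior means of the factors at the training
#' observations, on the natural scale of the model: for nonnegative
#' families the lognormal mean `exp(m + v / 2)` of `e^f` (and `e^h`), for
#' real-valued families the Gaussian mean. These are the matrices fed to
#' the simplex postprocessing and the recovery metrics.
#'
#' @param model a `factor_model`.
#' @return list with `F` (N x T), `H` (N x (L-T)), `W` (J x T),
#'   `V` (J x (L-T)).
#' @export
model_factors <- function(model) {
  sm <- .spatial_moments(model, seq_len(model$cache$N))
  P <- model$params
  if (model$nonneg) {
    F <- exp(sm$mean + sm$var / 2)
    H <- exp(P$Hm + exp(2 * P$Hls) / 2)
  } else {
    F <- sm$mean
    H <- P$Hm
  }
  ld <- model_loadings(model)
  list(F = F, H = H, W = ld$W, V = ld$V)
}

#' Predicted mean outcome at arbitrary spatial locations
#'
#' Spatial factors are evaluated at the query locations through the sparse
#' variational GP predictive moments; the contribution of `e^f` uses the
#' lognormal mean `exp(m + v / 2)`. Nonspatial factors are undefined at
#' unseen observations, so their contribution uses the training-population
#' average of the posterior factor means (`mean_i exp(Hm_il + Hs_il^2 / 2)`
#' for nonnegative families, `mean_i Hm_il` for real ones) — the natural
#' point prediction for the nonspatial activity of a new observation, and
#' better calibrated than the fitted prior's lognormal mean when the
#' aggregated posterior is far from Gaussian (e.g. bimodal on/off factors).
#'
#' For count likelihoods the returned matrix is the predicted mean count
#' `nu_i lambda_ij`. For Gaussian families it is the predicted
#' centered log-normalized value; see [predicted_counts()] for a
#' counts-scale prediction.
#'
#' @param model a `factor_model`.
#' @param X_new N_new x D coordinates.
#' @param nu_new length-N_new size factors (count families; default 1).
#' @return N_new x J matrix of predicted means.
#' @export
predict_mean <- function(model, X_new, nu_new = NULL) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != model$cache$D) stop("coordinate dimension mismatch")
  n <- nrow(X_new)
  P <- model$params
  Fpt <- matrix(0, n, model$T)
  if (model$T > 0) {
    Xq <- rescale_coords(X_new, model$cache$transform)
    a <- exp(P$log_a)
    for (l in seq_len(model$T)) {
      spec <- kernel_spec(model$kernel, amplitude = a[l],
                          lengthscale = model$lengthscale)
      state <- svgp_state(model$cache$Z, P$Qmu[, l], .qs_mat(P$Qs[, , l]),
                          jitter = model$jitter)
      pr <- svgp_predict(state, spec, mean_function(P$beta0[l], P$beta1[, l]), Xq)
      Fpt[, l] <- if (model$nonneg) exp(pr$mean + pr$var / 2) else pr$mean
    }
  }
  Hpt <- if (model$Lns > 0) {
    hbar <- if (model$nonneg) {
      colMeans(exp(P$Hm + exp(2 * P$Hls) / 2))
    } else {
      colMeans(P$Hm)
    }
    matrix(hbar, n, model$Lns, byrow = TRUE)
  } else {
    matrix(0, n, 0)
  }
  ld <- model_loadings(model)
  Mu <- Fpt %*% t(ld$W) + Hpt %*% t(ld$V)
  if (model$likelihood == "gaussian") return(Mu)
  if (is.null(nu_new)) nu_new <- rep(1, n)
  pmax(nu_new * Mu, 1e-10)
}

#' Counts-scale predictions for any model family
#'
#' For count-likelihood models this is [predict_mean()] with the given
#' size factors. Gaussian-likelihood models predict on the centered
#' log-normalized scale; the prediction is mapped back to counts by
#' undoing the centering, the log1p, and the median-total rescaling (the
#' total counts of the new observations supply the rescaling, mirroring
#' how the normalization was applied).
#'
#' @param model a `factor_model`.
#' @param X_new coordinates of the new observations.
#' @param nu_new size factors (count families).
#' @param totals_new total counts of the new observations (Gaussian
#'   families).
#' @return N_new x J matrix of strictly positive predicted counts.
#' @export
predicted_counts <- function(model, X_new, nu_new = NULL, totals_new = NULL) {
  if (model$likelihood != "gaussian") {
    return(predict_mean(model, X_new, nu_new = nu_new))
  }
  Mu <- predict_mean(model, X_new)
  Mu <- sweep(Mu, 2, model$cache$centering_means, "+")
  C <- pmax(expm1(Mu), 0)
  if (is.null(totals_new)) totals_new <- rep(model$cache$median_total, nrow(C))
  pmax(C * (totals_new / model$cache$median_total), 1e-10)
}
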