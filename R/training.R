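#' SVD initialization for real-valued factor models
#'
#' Rank-L truncated SVD of the normalized data: `F0 = U_L S_L`,
#' `W0 = V_L`, so `F0 W0'` is the best rank-L approximation.
#'
#' @param Y_tilde N x J normalized (centered) matrix.
#' @param L number of components (<= min(N, J)).
#' @return list with `F` (N x L) and `W` (J x L).
#' @export
init_real <- function(Y_tilde, L) {
  Y_tilde <- as.matrix(Y_tilde)
  if (L > min(dim(Y_tilde))) stop("L must not exceed min(N, J)")
  sv <- svd(Y_tilde, nu = L, nv = L)
  list(F = sv$u %*% diag(sv$d[seq_len(L)], L), W = sv$v)
}

#' Nonnegative matrix factorization initialization for count models
#'
#' Multiplicative-update NMF minimizing the generalized Kullback-Leibler
#' (Poisson) divergence to the size-factor-adjusted counts `Y / nu`,
#' giving nonnegative `F0` (N x L) and `W0` (J x L) with
#' `Y / nu ~ F0 W0'`. Seeded and deterministic.
#'
#' @param Y N x J count matrix.
#' @param L number of components (<= min(N, J)).
#' @param seed integer seed for the random initialization.
#' @param nu optional size factors dividing the rows of Y before fitting.
#' @param n_iter number of multiplicative updates (default 200).
#' @return list with nonnegative `F` and `W`.
#' @export
init_nonneg <- function(Y, L, seed = 1, nu = NULL, n_iter = 200) {
  Y <- as.matrix(Y)
  if (L > min(dim(Y))) stop("L must not exceed min(N, J)")
  if (!is.null(nu)) Y <- Y / nu
  N <- nrow(Y); J <- ncol(Y)
  eps <- 1e-10
  set.seed(seed)
  scale0 <- sqrt(mean(Y) / L)
  F <- matrix(stats::runif(N * L, 0.5, 1.5) * scale0, N, L)
  W <- matrix(stats::runif(J * L, 0.5, 1.5) * scale0, J, L)
  for (it in seq_len(n_iter)) {
    R <- Y / pmax(F %*% t(W), eps)
    F <- F * (R %*% W) / pmax(rep(colSums(W), each = N), eps)
    R <- Y / pmax(F %*% t(W), eps)
    W <- W * (t(R) %*% F) / pmax(rep(colSums(F), each = J), eps)
  }
  list(F = F, W = W)
}

#' Symmetric k-nearest-neighbour spatial adjacency
#'
#' Binary weights; `w_ij = 1` when j is among the k nearest neighbours of i
#' or vice versa. This is the pinned adjacency used for Moran's I on grid
#' and spot layouts.
#'
#' @param X N x D coordinates.
#' @param k neighbours per observation (default 6).
#' @return N x N sparse symmetric 0/1 matrix with zero diagonal.
#' @export
knn_graph <- function(X, k = 6) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 2) stop("need at least two observations")
  k <- min(k, N - 1)
  D <- .cross_dist(X, X)
  diag(D) <- Inf
  idx <- apply(D, 1, function(d) order(d)[seq_len(k)])
  i <- rep(seq_len(N), each = k)
  j <- as.integer(idx)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(N, N))
  W <- (W + Matrix::t(W) > 0) * 1
  methods::as(W, "generalMatrix")
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (N / sum(w)) * sum_ij w_ij (z_i - zbar)(z_j - zbar) /
#' sum_i (z_i - zbar)^2`. Positive for spatially clustered values, near
#' zero for spatially random ones, negative for dispersed patterns. A
#' constant vector has undefined variance; by convention 0 is returned
#' with a warning so that rankings over factor columns remain total.
#'
#' @param z length-N numeric vector.
#' @param adjacency N x N symmetric nonnegative weight matrix (dense or
#'   sparse) with at least one positive weight.
#' @return scalar Moran's I.
#' @export
morans_i <- function(z, adjacency) {
  N <- length(z)
  if (N < 2) stop("need at least two observations")
  if (!all(dim(adjacency) == c(N, N))) stop("adjacency must be N x N")
  wsum <- sum(adjacency)
  if (wsum <= 0) stop("adjacency must contain at least one positive weight")
  zc <- z - mean(z)
  denom <- sum(zc^2)
  if (denom < .Machine$double.eps * N) {
    warning("constant vector: Moran's I undefined, returning 0")
    return(0)
  }
  num <- sum(zc * as.numeric(adjacency %*% zc))
  (N / wsum) * num / denom
}

#' Order initial components by decreasing spatial autocorrelation
#'
#' Computes Moran's I for each factor column on the pinned k-NN adjacency
#' and permutes factors and loadings jointly in decreasing order; the
#' first `T` components are assigned to the spatial block. The permutation
#' leaves the reconstruction `F0 W0'` unchanged.
#'
#' @param F0 N x L initial factors.
#' @param W0 J x L initial loadings.
#' @param X N x D coordinates.
#' @param T number of spatial components (<= L).
#' @param k k-NN parameter for the adjacency (default 6).
#' @return list with permuted `F`, `W`, the Moran's I values `moran` (in
#'   the permuted order) and `spatial` (indices `1:T` of the spatial
#'   block).
#' @export
sort_components_by_moran <- function(F0, W0, X, T, k = 6) {
  F0 <- as.matrix(F0); W0 <- as.matrix(W0)
  L <- ncol(F0)
  if (T > L) stop("T must not exceed the number of components")
  I <- suppressWarnings(factor_morans_i(F0, X, k = k))
  ord <- order(I, decreasing = TRUE)
  list(F = F0[, ord, drop = FALSE], W = W0[, ord, drop = FALSE],
       moran = I[ord], spatial = seq_len(T))
}

#' Smoothed-trace convergence detection for stochastic optimizers
#'
#' Monte-Carlo objectives fluctuate, so convergence is declared on a
#' smoothed trace: starting at iteration `start` (default 110) and
#' repeating every `stride` (10) iterations, a cubic polynomial is fit by
#' least squares to the most recent `window` (100) raw objective values.
#' The smoothed objective at the current and at the previous check's
#' iteration are both evaluated from the current polynomial; convergence
#' is declared when their relative change is below `tol` (5e-5).
#'
#' @param trace numeric vector of raw objective values, one per iteration.
#' @param start first iteration checked (default 110).
#' @param window number of recent values in the cubic fit (default 100).
#' @param stride iterations between checks (default 10).
#' @param tol relative-change threshold (default 5e-5).
#' @return the iteration at which convergence was first declared, or
#'   `NULL` if the trace never converged (including traces shorter than
#'   `start`).
#' @export
check_convergence <- function(trace, start = 110, window = 100, stride = 10,
                              tol = 5e-5) {
  n <- length(trace)
  if (n < start) return(NULL)
  for (t in seq(start, n, by = stride)) {
    y <- trace[(t - window + 1):t]
    x <- seq(t - window + 1, t)
    xs <- 2 * (x - mean(x)) / (max(x) - min(x))  # center/scale to [-1, 1]
    fit <- stats::lm.fit(cbind(1, xs, xs^2, xs^3), y)
    co <- fit$coefficients
    sm <- function(xi) {
      z <- 2 * (xi - mean(x)) / (max(x) - min(x))
      sum(co * c(1, z, z^2, z^3))
    }
    now <- sm(t)
    prev <- sm(t - stride)
    rel <- abs(now - prev) / max(abs(prev), .Machine$double.eps)
    if (rel < tol) return(t)
  }
  NULL
}

#' Optimization settings for model fitting
#'
#' Defaults: 3 Monte-Carlo ELBO samples, Adam with learning rate 0.01,
#' full batches for N <= 3000 (otherwise 1000), up to 1000 iterations, and
#' the smoothed-trace convergence constants (start 110, window 100,
#' stride 10, tolerance 5e-5).
#'
#' @param n_samples_elbo Monte-Carlo samples per ELBO evaluation.
#' @param batch_size minibatch size, or `NULL` for the N-dependent default.
#' @param learning_rate Adam step size.
#' @param max_iter maximum iterations.
#' @param seed integer seed for all fitting stochasticity.
#' @param conv_start,conv_window,conv_stride,conv_tol convergence-detector
#'   constants; see [check_convergence()].
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_samples_elbo = 3, batch_size = NULL,
                       learning_rate = 0.01, max_iter = 1000, seed = 1,
                       conv_start = 110, conv_window = 100, conv_stride = 10,
                       conv_tol = 5e-5) {
  stopifnot(n_samples_elbo >= 1, learning_rate > 0, max_iter >= 1)
  structure(
    list(n_samples_elbo = as.integer(n_samples_elbo),
         batch_size = batch_size, learning_rate = learning_rate,
         max_iter = as.integer(max_iter), seed = as.integer(seed),
         conv_start = conv_start, conv_window = conv_window,
         conv_stride = conv_stride, conv_tol = conv_tol),
    class = "fit_config"
  )
}
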