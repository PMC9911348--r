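#' Kernel specification
#'
#' @param family `"matern32"` (Matern with smoothness 3/2, the default) or
#'   `"eq"` (exponentiated quadratic / squared exponential).
#' @param amplitude positive amplitude `a`; the prior variance is `a^2`.
#' @param lengthscale positive lengthscale.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("matern32", "eq"), amplitude = 1,
                        lengthscale = 0.1) {
  family <- match.arg(family)
  if (amplitude <= 0 || lengthscale <= 0) {
    stop("amplitude and lengthscale must be strictly positive")
  }
  structure(list(family = family, amplitude = amplitude,
                 lengthscale = lengthscale),
            class = "kernel_spec")
}

#' Linear mean function of the spatial coordinates
#'
#' `mu(x) = beta0 + x' beta1`, the parametric GP mean used for each spatial
#' component.
#'
#' @param beta0 intercept.
#' @param beta1 length-D slope vector.
#' @return object of class `mean_function`.
#' @export
mean_function <- function(beta0 = 0, beta1 = c(0, 0)) {
  if (!all(is.finite(c(beta0, beta1)))) stop("mean coefficients must be finite")
  structure(list(beta0 = beta0, beta1 = as.numeric(beta1)),
            class = "mean_function")
}

#' @rdname mean_function
#' @param X N x D coordinate matrix.
#' @param mean a [mean_function()].
#' @return `linear_mean`: length-N vector of mean values.
#' @export
linear_mean <- function(X, mean) {
  X <- as.matrix(X)
  if (ncol(X) != length(mean$beta1)) {
    stop("coordinate dimension does not match length of beta1")
  }
  as.numeric(mean$beta0 + X %*% mean$beta1)
}

# Euclidean cross-distance matrix.
.cross_dist <- function(X1, X2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  sqrt(pmax(d2, 0))
}

#' Kernel (covariance) matrix between two coordinate sets
#'
#' Matern 3/2: `k(r) = a^2 (1 + sqrt(3) r / l) exp(-sqrt(3) r / l)`;
#' EQ: `k(r) = a^2 exp(-r^2 / (2 l^2))`, with `r` the Euclidean distance.
#'
#' @param X1,X2 coordinate matrices with matching column dimension.
#' @param spec a [kernel_spec()].
#' @return `nrow(X1)` x `nrow(X2)` covariance matrix.
#' @export
kernel_matrix <- function(X1, X2, spec) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) stop("coordinate dimensions must match")
  r <- .cross_dist(X1, X2)
  a2 <- spec$amplitude^2
  l <- spec$lengthscale
  switch(spec$family,
    matern32 = {
      s <- sqrt(3) * r / l
      a2 * (1 + s) * exp(-s)
    },
    eq = a2 * exp(-r^2 / (2 * l^2))
  )
}

# Cholesky with an escalating jitter ladder. Returns the lower factor.
# The jitter is scaled by the prior variance so behaviour is amplitude-free.
.chol_jitter <- function(K, scale = 1, ladder = c(1e-6, 1e-4, 1e-2)) {
  n <- nrow(K)
  for (j in ladder) {
    L <- tryCatch(t(chol(K + diag(j * scale, n))), error = function(e) NULL)
    if (!is.null(L)) {
      attr(L, "jitter") <- j
      return(L)
    }
  }
  stop("Cholesky factorization failed even with jitter ", max(ladder),
       "; kernel matrix is numerically degenerate (n = ", n, ")")
}

#' Sparse variational GP state (whitened parameterization)
#'
#' Holds the inducing locations and the whitened variational distribution
#' `q(u) = N(mu(Z) + L q_mu, L S S' L')` where `L` is the Cholesky factor
#' of the inducing-point prior covariance and `S = q_sqrt` is
#' lower-triangular with positive diagonal. `q_mu = 0`, `q_sqrt = I`
#' reproduces the GP prior.
#'
#' @param Z M x D inducing locations.
#' @param q_mu length-M whitened variational mean (default 0).
#' @param q_sqrt M x M lower-triangular variational covariance root with
#'   positive diagonal (default identity).
#' @param jitter relative diagonal jitter for Cholesky stability.
#' @return object of class `svgp_state`.
#' @export
svgp_state <- function(Z, q_mu = NULL, q_sqrt = NULL, jitter = 1e-6) {
  Z <- as.matrix(Z)
  M <- nrow(Z)
  if (is.null(q_mu)) q_mu <- rep(0, M)
  if (is.null(q_sqrt)) q_sqrt <- diag(M)
  if (length(q_mu) != M) stop("q_mu must have length M")
  if (!all(dim(q_sqrt) == c(M, M))) stop("q_sqrt must be M x M")
  if (any(q_sqrt[upper.tri(q_sqrt)] != 0)) stop("q_sqrt must be lower-triangular")
  if (any(diag(q_sqrt) <= 0)) stop("q_sqrt must have a strictly positive diagonal")
  structure(list(Z = Z, q_mu = as.numeric(q_mu), q_sqrt = q_sqrt,
                 jitter = jitter),
            class = "svgp_state")
}

#' Predictive moments of a sparse variational GP
#'
#' Standard inducing-point predictive equations in the whitened
#' parameterization: with `A = L^{-1} K_{Z,q}`,
#' `mean = mu(Xq) + A' q_mu` and
#' `var = k(x,x) - colSums(A^2) + colSums((q_sqrt' A)^2)`.
#'
#' @param state an [svgp_state()].
#' @param spec a [kernel_spec()].
#' @param mean a [mean_function()].
#' @param Xq query coordinates.
#' @return list with numeric vectors `mean` and `var` (strictly positive).
#' @export
svgp_predict <- function(state, spec, mean, Xq) {
  Xq <- as.matrix(Xq)
  if (ncol(Xq) != ncol(state$Z)) stop("query coordinate dimension mismatch")
  Kzz <- kernel_matrix(state$Z, state$Z, spec)
  L <- .chol_jitter(Kzz, scale = spec$amplitude^2,
                    ladder = c(state$jitter, 1e-4, 1e-2))
  A <- forwardsolve(L, kernel_matrix(state$Z, Xq, spec))
  mu <- linear_mean(Xq, mean) + as.numeric(crossprod(A, state$q_mu))
  kdiag <- rep(spec$amplitude^2, nrow(Xq))  # stationary kernels
  SA <- crossprod(state$q_sqrt, A)
  v <- kdiag - colSums(A^2) + colSums(SA^2)
  list(mean = mu, var = pmax(v, 1e-12))
}

#' KL divergence of the whitened variational distribution from the prior
#'
#' `KL = (||q_mu||^2 + ||q_sqrt||_F^2 - M - 2 sum(log diag(q_sqrt))) / 2`,
#' nonnegative with equality iff `q_mu = 0`, `q_sqrt = I`.
#'
#' @param state an [svgp_state()].
#' @return nonnegative scalar.
#' @export
svgp_kl <- function(state) {
  d <- diag(state$q_sqrt)
  if (any(d <= 0)) stop("q_sqrt diagonal must be strictly positive")
  0.5 * (sum(state$q_mu^2) + sum(state$q_sqrt^2) - length(state$q_mu) -
           2 * sum(log(d)))
}

#' Choose inducing-point locations
#'
#' @param X N x D training coordinates.
#' @param M number of inducing points (ignored for `strategy = "all"`).
#' @param strategy `"all"` (unique rows of X, the default for small
#'   datasets), `"kmeans"` (M k-means centroids) or `"random"` (M sampled
#'   rows).
#' @param seed integer seed for the stochastic strategies.
#' @return matrix of inducing locations.
#' @export
choose_inducing_points <- function(X, M = NULL,
                                   strategy = c("all", "kmeans", "random"),
                                   seed = 1) {
  strategy <- match.arg(strategy)
  X <- as.matrix(X)
  if (strategy == "all") return(unique(X))
  if (is.null(M)) stop("M is required for strategy '", strategy, "'")
  if (M > nrow(X)) stop("M must not exceed the number of observations")
  set.seed(seed)
  if (strategy == "random") {
    return(X[sample.int(nrow(X), M), , drop = FALSE])
  }
  if (M >= nrow(unique(X))) {
    # each point is its own centroid; kmeans itself is unreliable at k = n
    return(unique(X)[seq_len(min(M, nrow(unique(X)))), , drop = FALSE])
  }
  km <- stats::kmeans(X, centers = M, iter.max = 100, nstart = 1)
  km$centers
}

# Rescale coordinates so the longest side of the bounding box has length 1,
# preserving aspect ratio. Returns the rescaled matrix plus the transform.
rescale_coords <- function(X, transform = NULL) {
  X <- as.matrix(X)
  if (is.null(transform)) {
    mins <- apply(X, 2, min)
    span <- max(apply(X, 2, max) - mins)
    if (span <= 0) span <- 1
    transform <- list(mins = mins, span = span)
  }
  Xs <- sweep(X, 2, transform$mins) / transform$span
  attr(Xs, "transform") <- transform
  Xs
}
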