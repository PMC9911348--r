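#' Mean Poisson deviance between counts and predicted means
#'
#' Per-entry deviance `2 [y log(y / mu) - (y - mu)]` (with `0 log 0 = 0`),
#' summed over features and averaged over observations. Zero iff the
#' prediction matches the counts exactly.
#'
#' @param y N x J observed counts (a vector is treated as one observation).
#' @param mu N x J strictly positive predicted means.
#' @return nonnegative scalar.
#' @export
mean_poisson_deviance <- function(y, mu) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  if (!all(dim(y) == dim(mu))) stop("y and mu must have matching dimensions")
  if (any(mu <= 0)) stop("predicted means must be strictly positive")
  d <- .poisson_deviance_terms(as.matrix(y), as.matrix(mu))
  mean(rowSums(d))
}

#' Root mean squared error
#'
#' @param y,pred numeric arrays of matching shape.
#' @return nonnegative scalar.
#' @export
rmse <- function(y, pred) {
  if (length(y) != length(pred)) stop("inputs must have matching length")
  sqrt(mean((as.numeric(y) - as.numeric(pred))^2))
}

#' Match fitted factors to ground truth by absolute Pearson correlation
#'
#' For each true column, the best-matching fitted column is the one with
#' the highest absolute Pearson correlation; the summary statistic is the
#' minimum of these best correlations over true columns (high minimum =
#' every true factor was recovered by some fitted factor). The same routine
#' applies to loadings matrices. Correlations involving a constant column
#' are defined as 0 so the summary is always well defined.
#'
#' @param F_hat N x L fitted factors (or loadings).
#' @param F_true N x L_true true factors (or loadings).
#' @return list with `per_factor` (length-L_true best |r| per true column)
#'   and `min` (minimum over true columns).
#' @export
match_factors <- function(F_hat, F_true) {
  F_hat <- as.matrix(F_hat); F_true <- as.matrix(F_true)
  if (nrow(F_hat) != nrow(F_true)) stop("row dimensions must match")
  cc <- suppressWarnings(stats::cor(F_true, F_hat))
  cc[!is.finite(cc)] <- 0
  per <- apply(abs(cc), 1, max)
  list(per_factor = as.numeric(per), min = min(per))
}

#' Fraction of (near-)zero entries in a loadings matrix
#'
#' Entries with `|w| <= tol * max(|W|)` count as zero. The relative
#' tolerance matters because exponentially-parameterized nonnegative models
#' produce strictly positive loadings whose "zeros" are merely tiny.
#'
#' @param W loadings matrix (nonempty).
#' @param tol relative tolerance (default 1e-6).
#' @return fraction in [0, 1].
#' @export
loadings_sparsity <- function(W, tol = 1e-6) {
  W <- as.matrix(W)
  if (length(W) == 0) stop("W must be nonempty")
  if (tol < 0) stop("tol must be nonnegative")
  mean(abs(W) <= tol * max(abs(W)))
}

#' Euclidean distance between estimated and true spatial importance scores
#'
#' @param gamma_hat,gamma_true numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
score_recovery_distance <- function(gamma_hat, gamma_true) {
  if (length(gamma_hat) != length(gamma_true)) stop("lengths must match")
  sqrt(sum((gamma_hat - gamma_true)^2))
}

#' Moran's I of each factor column over a spatial domain
#'
#' Builds the pinned symmetric k-nearest-neighbour adjacency (binary
#' weights) once and applies [morans_i()] to each column.
#'
#' @param F N x L factor matrix.
#' @param X N x D coordinates.
#' @param k number of nearest neighbours (default 6).
#' @return length-L numeric vector of Moran's I values.
#' @export
factor_morans_i <- function(F, X, k = 6) {
  F <- as.matrix(F)
  Wadj <- knn_graph(X, k = k)
  apply(F, 2, function(z) morans_i(z, Wadj))
}
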