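#' Draw a matrix of negative binomial counts
#'
#' Samples entries i.i.d. from a negative binomial distribution
#' parameterized by mean and shape, with `Var = mean + mean^2 / shape`.
#' In the classical (r, p) parameterization this corresponds to
#' `r = shape` and `p = shape / (shape + mean)`. Large shapes approach the
#' Poisson limit.
#'
#' @param mean matrix (or vector) of strictly positive means.
#' @param shape positive dispersion ("shape") parameter; shared by all entries.
#' @param seed optional integer seed. If `NULL`, draws consume the current
#'   RNG stream (used internally so a whole simulated dataset is keyed by a
#'   single seed).
#' @return integer matrix with the same dimensions as `mean`.
#' @export
draw_negative_binomial <- function(mean, shape, seed = NULL) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    stop("all means must be finite and strictly positive")
  }
  if (!is.numeric(shape) || length(shape) != 1 || shape <= 0) {
    stop("shape must be a single positive number")
  }
  if (!is.null(seed)) set.seed(seed)
  y <- stats::rnbinom(length(mean), mu = as.numeric(mean), size = shape)
  if (is.null(dim(mean))) return(y)
  matrix(y, nrow = nrow(mean), ncol = ncol(mean))
}

# Container for simulation ground truth.
simulation_truth <- function(F, H, W, V, mean_matrix, true_gene_scores,
                             coords, seed) {
  structure(
    list(F = F, H = H, W = W, V = V, mean_matrix = mean_matrix,
         true_gene_scores = true_gene_scores, coords = coords, seed = seed),
    class = "simulation_truth"
  )
}

#' @method print simulation_truth
#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d obs, %d spatial + %d nonspatial factors, %d features (seed %d)\n",
              nrow(x$F), ncol(x$F), if (is.null(x$H)) 0L else ncol(x$H),
              nrow(x$W), x$seed))
  invisible(x)
}

# One-hot loadings: each feature assigned one component uniformly at random,
# with the given weight. Consumes the current RNG stream.
.one_hot_loadings <- function(n_features, n_components, weight) {
  assign <- sample.int(n_components, n_features, replace = TRUE)
  W <- matrix(0, n_features, n_components)
  W[cbind(seq_len(n_features), assign)] <- weight
  W
}

#' Simulate scenario-I spatial count data (spatial factors only)
#'
#' Generates counts from binary spatial factor patterns: each feature is
#' assigned uniformly at random to one pattern with one-hot loading weight
#' 20, the mean matrix is `0.2 + F W'` (so active cells have mean 20.2 and
#' background cells 0.2), and counts are negative binomial with shape 10.
#'
#' @param pattern `"ggblocks"`, `"quilt"` or `"both"`.
#' @param n_features number of features J (default 200).
#' @param seed integer seed; assignment and count draws consume a single
#'   stream keyed by this seed (assignments first, then counts).
#' @param grid_side grid side length (default 36, i.e. N = 1296).
#' @param shape negative binomial shape (default 10). Very large values give
#'   the Poisson limit, useful for testing the sampler.
#' @param loading_weight active loading weight (default 20).
#' @return list with elements `data` ([count_dataset]) and `truth`
#'   ([simulation_truth]; `H` and `V` are `NULL`).
#' @export
simulate_scenario1 <- function(pattern = c("ggblocks", "quilt", "both"),
                               n_features = 200, seed = 1, grid_side = 36,
                               shape = 10, loading_weight = 20) {
  pattern <- match.arg(pattern)
  if (n_features < 1) stop("n_features must be >= 1")
  lib <- pattern_library(pattern, grid_side)
  F <- lib$factors
  set.seed(seed)
  W <- .one_hot_loadings(n_features, ncol(F), loading_weight)
  M <- 0.2 + F %*% t(W)
  Y <- draw_negative_binomial(M, shape)
  truth <- simulation_truth(
    F = F, H = NULL, W = W, V = NULL, mean_matrix = M,
    true_gene_scores = gene_spatial_scores(W, NULL, F, NULL),
    coords = lib$coords, seed = seed
  )
  list(
    data = count_dataset(Y, lib$coords),
    truth = truth
  )
}

#' Simulate scenario-II spatial count data (spatial + nonspatial factors)
#'
#' Adds nonspatial binary factors (entries Bernoulli(0.2)) to the spatial
#' patterns: 3 nonspatial factors for the four-pattern libraries, 6 for
#' `"both"`. In `"split"` mode the first half of the features load (weight
#' 20) on one spatial component only and the second half on one nonspatial
#' component only; in `"mixed"` mode every feature has one spatial entry of
#' 12 and one nonspatial entry of 8. The mean matrix is
#' `0.2 + F W' + H V'`; counts are negative binomial with shape 10.
#' Ground-truth gene spatial importance scores are computed from the truth
#' matrices with [gene_spatial_scores()].
#'
#' @inheritParams simulate_scenario1
#' @param loading_mode `"split"` or `"mixed"`.
#' @param n_features number of features J (default 500; must be even for
#'   `"split"`).
#' @return list with elements `data` and `truth` as in
#'   [simulate_scenario1()].
#' @export
simulate_scenario2 <- function(pattern = c("ggblocks", "quilt", "both"),
                               loading_mode = c("split", "mixed"),
                               n_features = 500, seed = 1, grid_side = 36,
                               shape = 10) {
  pattern <- match.arg(pattern)
  loading_mode <- match.arg(loading_mode)
  if (n_features < 1) stop("n_features must be >= 1")
  if (loading_mode == "split" && n_features %% 2 != 0) {
    stop("n_features must be even for the split loading mode")
  }
  lib <- pattern_library(pattern, grid_side)
  F <- lib$factors
  Tn <- ncol(F)
  n_nonsp <- if (Tn == 8) 6L else 3L
  N <- nrow(F)
  set.seed(seed)
  # RNG stream order: nonspatial factor draws, loading assignments, counts.
  H <- matrix(stats::rbinom(N * n_nonsp, 1, 0.2), N, n_nonsp)
  if (loading_mode == "split") {
    half <- n_features %/% 2
    W <- rbind(.one_hot_loadings(half, Tn, 20),
               matrix(0, half, Tn))
    V <- rbind(matrix(0, half, n_nonsp),
               .one_hot_loadings(half, n_nonsp, 20))
  } else {
    W <- .one_hot_loadings(n_features, Tn, 12)
    V <- .one_hot_loadings(n_features, n_nonsp, 8)
  }
  M <- 0.2 + F %*% t(W) + H %*% t(V)
  Y <- draw_negative_binomial(M, shape)
  truth <- simulation_truth(
    F = F, H = H, W = W, V = V, mean_matrix = M,
    true_gene_scores = gene_spatial_scores(W, V, F, H),
    coords = lib$coords, seed = seed
  )
  list(
    data = count_dataset(Y, lib$coords),
    truth = truth
  )
}
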