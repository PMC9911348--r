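#' Construct a spatial count dataset
#'
#' Bundles a counts matrix with spatial coordinates, per-observation size
#' factors and optional train/validation masks. This is the common input
#' container for all factor models in the package.
#'
#' @param Y N x J matrix of nonnegative integer counts (dense or a
#'   `Matrix` sparse matrix). Rows are observations (spots, cells,
#'   locations), columns are features (genes).
#' @param X N x D matrix of spatial coordinates (D = 2 typical).
#' @param nu length-N vector of positive size factors. Defaults to 1 for
#'   every observation (appropriate for simulated data); use
#'   [compute_size_factors()] for sequencing data.
#' @param feature_ids optional length-J character vector of feature labels.
#' @param train_mask optional length-N logical vector, `TRUE` for training
#'   observations.
#' @return An object of class `count_dataset`: a list with elements
#'   `Y`, `X`, `nu`, `feature_ids`, `train_mask`.
#' @export
count_dataset <- function(Y, X, nu = NULL, feature_ids = NULL, train_mask = NULL) {
  if (is.null(dim(Y))) stop("Y must be a matrix")
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) {
    stop("Y and X must have the same number of rows (observations)")
  }
  if (min(Y) < 0) stop("Y must be nonnegative")
  if (is.null(nu)) nu <- rep(1, nrow(Y))
  if (length(nu) != nrow(Y)) stop("nu must have one entry per observation")
  if (any(nu <= 0)) stop("size factors nu must be strictly positive")
  if (is.null(feature_ids)) {
    feature_ids <- colnames(Y)
    if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(ncol(Y)))
  }
  if (length(feature_ids) != ncol(Y)) stop("feature_ids must have one entry per feature")
  if (!is.null(train_mask)) {
    if (length(train_mask) != nrow(Y) || !is.logical(train_mask)) {
      stop("train_mask must be a logical vector with one entry per observation")
    }
  }
  structure(
    list(Y = Y, X = X, nu = as.numeric(nu), feature_ids = feature_ids,
         train_mask = train_mask),
    class = "count_dataset"
  )
}

#' @method print count_dataset
#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("<count_dataset> %d observations x %d features, %d spatial dims\n",
              nrow(x$Y), ncol(x$Y), ncol(x$X)))
  if (!is.null(x$train_mask)) {
    cat(sprintf("  train/validation: %d / %d\n",
                sum(x$train_mask), sum(!x$train_mask)))
  }
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$Y)

# Subset a dataset by observation index (used for train/validation splits).
subset_obs <- function(data, idx) {
  count_dataset(
    Y = data$Y[idx, , drop = FALSE],
    X = data$X[idx, , drop = FALSE],
    nu = data$nu[idx],
    feature_ids = data$feature_ids,
    train_mask = NULL
  )
}
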