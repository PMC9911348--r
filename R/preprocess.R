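#' Per-observation size factors
#'
#' Size factors are total counts per observation divided by the median
#' total, so that the median size factor is 1.
#'
#' @param Y N x J count matrix (dense or sparse).
#' @return length-N numeric vector of positive size factors.
#' @export
compute_size_factors <- function(Y) {
  totals <- as.numeric(Matrix::rowSums(Y))
  bad <- which(totals <= 0)
  if (length(bad) > 0) {
    stop("observations with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  totals / stats::median(totals)
}

# Poisson deviance of a count vector y against fitted means mu, with the
# convention 0 * log 0 = 0.
.poisson_deviance_terms <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * (term - (y - mu))
}

#' Rank features by Poisson deviance against a constant-expression null
#'
#' For each gene j the null model is `yhat_ij = nu_i * sum_i(y_ij) /
#' sum_i(nu_i)` (constant expression up to size factors); genes are ranked
#' by the Poisson deviance of their counts against this null. Highly
#' deviant genes are informative: their expression varies beyond what
#' sequencing depth explains.
#'
#' @param Y N x J count matrix.
#' @param n_top number of top features to return (<= J).
#' @param nu optional size factors; computed with [compute_size_factors()]
#'   when missing.
#' @return integer vector of `n_top` feature indices in decreasing order of
#'   deviance, with the deviances attached as attribute `"deviance"`.
#' @export
select_informative_genes <- function(Y, n_top = 2000, nu = NULL) {
  J <- ncol(Y)
  if (n_top > J) stop("n_top must not exceed the number of features")
  if (is.null(nu)) nu <- compute_size_factors(Y)
  Y <- as.matrix(Y)
  gene_totals <- colSums(Y)
  rates <- gene_totals / sum(nu)        # per-gene expression rate
  dev <- vapply(seq_len(J), function(j) {
    mu <- nu * rates[j]
    if (all(mu == 0)) return(0)
    sum(.poisson_deviance_terms(Y[, j], pmax(mu, .Machine$double.xmin)))
  }, numeric(1))
  ord <- order(dev, decreasing = TRUE)
  idx <- ord[seq_len(n_top)]
  attr(idx, "deviance") <- dev[idx]
  idx
}

#' Log-normalize and center counts for Gaussian-likelihood models
#'
#' Counts are rescaled so every observation's total equals the median
#' total, log transformed with a pseudocount of one, and the features are
#' centered to mean zero.
#'
#' @param Y N x J count matrix with positive row totals.
#' @return An object of class `normalized_dataset`: list with `Y_tilde`
#'   (N x J centered log-normalized values) and `centering_means`
#'   (length-J feature means removed in the final step).
#' @export
lognormalize_center <- function(Y) {
  totals <- as.numeric(Matrix::rowSums(Y))
  bad <- which(totals <= 0)
  if (length(bad) > 0) {
    stop("observations with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  med <- stats::median(totals)
  Yl <- log1p(as.matrix(Y) * (med / totals))
  mu <- colMeans(Yl)
  structure(
    list(Y_tilde = sweep(Yl, 2, mu), centering_means = mu,
         median_total = med),
    class = "normalized_dataset"
  )
}

#' Random train/validation split of observations
#'
#' The validation size is `round(frac * N)` (round-half-even, as in base R,
#' for cross-platform reproducibility).
#'
#' @param N number of observations.
#' @param frac validation fraction in (0, 1) (default 0.05).
#' @param seed integer seed.
#' @return list with sorted integer index vectors `train` and `validation`
#'   partitioning `1:N`.
#' @export
split_train_validation <- function(N, frac = 0.05, seed = 1) {
  if (frac <= 0 || frac >= 1) stop("frac must be strictly between 0 and 1")
  n_val <- round(frac * N)
  if (n_val < 1 || n_val >= N) {
    stop("degenerate split: validation size would be ", n_val, " of ", N)
  }
  set.seed(seed)
  val <- sort(sample.int(N, n_val))
  list(train = setdiff(seq_len(N), val), validation = val)
}
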