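#' Simplex projection of a nonnegative factorization (SPDE style)
#'
#' Rescales a nonnegative factorization `Lambda = F W'` so the columns of
#' `F` each sum to one and the rows of `W` each sum to one, leaving the
#' product invariant: `Lambda = F W' diag(w_bar)` afterwards. Each row of
#' the projected `W` is then a feature's soft assignment across components.
#'
#' The steps, in order: `f_bar = colSums(F)`; `F <- F diag(f_bar)^{-1}`;
#' `W <- W diag(f_bar)`; `w_bar = rowSums(W)`; `W <- diag(w_bar)^{-1} W`.
#'
#' @param F N x L nonnegative factors with no all-zero column.
#' @param W J x L nonnegative loadings with no all-zero row.
#' @return object of class `simplex_factorization`: list with `F`, `W`,
#'   `w_bar` (length-J scaling) and `style = "spde"`.
#' @export
project_simplex_spde <- function(F, W) {
  F <- as.matrix(F); W <- as.matrix(W)
  if (ncol(F) != ncol(W)) stop("F and W must have the same number of components")
  if (min(F) < 0 || min(W) < 0) stop("F and W must be nonnegative")
  f_bar <- colSums(F)
  zc <- which(f_bar < 1e-12)
  if (length(zc) > 0) stop("all-zero factor column(s): ", paste(zc, collapse = ", "))
  F <- sweep(F, 2, f_bar, "/")
  W <- sweep(W, 2, f_bar, "*")
  w_bar <- rowSums(W)
  zr <- which(w_bar < 1e-12)
  if (length(zr) > 0) stop("all-zero loading row(s): ", paste(zr, collapse = ", "))
  W <- sweep(W, 1, w_bar, "/")
  structure(list(F = F, W = W, w_bar = w_bar, style = "spde"),
            class = "simplex_factorization")
}

#' Simplex projection of a nonnegative factorization (LDA style)
#'
#' The roles of factors and loadings are switched relative to
#' [project_simplex_spde()]: loadings columns sum to one ("topics") and
#' factor rows sum to one (a soft clustering of observations), with a
#' length-N scaling vector `f_bar` so that
#' `Lambda = diag(f_bar) F W'` afterwards.
#'
#' @inheritParams project_simplex_spde
#' @return object of class `simplex_factorization`: list with `F`, `W`,
#'   `f_bar` (length-N scaling) and `style = "lda"`.
#' @export
project_simplex_lda <- function(F, W) {
  F <- as.matrix(F); W <- as.matrix(W)
  if (ncol(F) != ncol(W)) stop("F and W must have the same number of components")
  if (min(F) < 0 || min(W) < 0) stop("F and W must be nonnegative")
  w_bar <- colSums(W)
  zc <- which(w_bar < 1e-12)
  if (length(zc) > 0) stop("all-zero loading column(s): ", paste(zc, collapse = ", "))
  W <- sweep(W, 2, w_bar, "/")
  F <- sweep(F, 2, w_bar, "*")
  f_bar <- rowSums(F)
  zr <- which(f_bar < 1e-12)
  if (length(zr) > 0) stop("all-zero factor row(s): ", paste(zr, collapse = ", "))
  F <- sweep(F, 1, f_bar, "/")
  structure(list(F = F, W = W, f_bar = f_bar, style = "lda"),
            class = "simplex_factorization")
}

#' @method print simplex_factorization
#' @export
print.simplex_factorization <- function(x, ...) {
  cat(sprintf("<simplex_factorization> %s style: F %d x %d, W %d x %d\n",
              x$style, nrow(x$F), ncol(x$F), nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Gene-level spatial importance scores
#'
#' For a hybrid factorization with spatial blocks `(F, W)` and nonspatial
#' blocks `(H, V)`, concatenate `A = [F, H]`, `B = [W, V]`, apply SPDE-style
#' simplex projection, and sum each feature's projected loadings over the
#' spatial components. The score `gamma_j` lies in [0, 1]: 1 means feature
#' j's variation is fully captured by the spatial components, 0 fully by
#' the nonspatial ones. All-spatial models (`T = L`) give scores of exactly
#' 1; all-nonspatial models (`T = 0`) give exactly 0.
#'
#' @param W_spatial J x T nonnegative spatial loadings (or `NULL` if T = 0).
#' @param V_nonspatial J x (L-T) nonnegative nonspatial loadings (or `NULL`
#'   if T = L).
#' @param F N x T nonnegative spatial factors (point estimates, e.g.
#'   posterior means of `e^f`).
#' @param H N x (L-T) nonnegative nonspatial factors.
#' @return length-J numeric vector of scores in [0, 1].
#' @export
gene_spatial_scores <- function(W_spatial, V_nonspatial, F, H) {
  Tn <- if (is.null(W_spatial)) 0L else ncol(W_spatial)
  Lns <- if (is.null(V_nonspatial)) 0L else ncol(V_nonspatial)
  if (Tn == 0 && Lns == 0) stop("at least one loading block is required")
  J <- if (Tn > 0) nrow(W_spatial) else nrow(V_nonspatial)
  if (Tn == 0) return(rep(0, J))
  if (Lns == 0) return(rep(1, J))
  A <- cbind(F, H)
  B <- cbind(W_spatial, V_nonspatial)
  proj <- project_simplex_spde(A, B)
  rowSums(proj$W[, seq_len(Tn), drop = FALSE])
}

#' Observation-level spatial importance scores
#'
#' LDA-style counterpart of [gene_spatial_scores()]: after LDA-style
#' projection of the concatenated factorization, sum each observation's
#' projected factor values over the spatial components. `rho_i` in [0, 1].
#'
#' @param F,H nonnegative spatial / nonspatial factor blocks (either may be
#'   `NULL` when empty).
#' @param W,V nonnegative spatial / nonspatial loading blocks.
#' @return length-N numeric vector of scores in [0, 1].
#' @export
observation_spatial_scores <- function(F, H, W, V) {
  Tn <- if (is.null(F)) 0L else ncol(F)
  Lns <- if (is.null(H)) 0L else ncol(H)
  if (Tn == 0 && Lns == 0) stop("at least one factor block is required")
  N <- if (Tn > 0) nrow(F) else nrow(H)
  if (Tn == 0) return(rep(0, N))
  if (Lns == 0) return(rep(1, N))
  A <- cbind(F, H)
  B <- cbind(W, V)
  proj <- project_simplex_lda(A, B)
  rowSums(proj$F[, seq_len(Tn), drop = FALSE])
}

#' Top-ranked features for one component of a simplex-projected loadings matrix
#'
#' @param W J x L loadings (typically simplex-projected).
#' @param component column index l.
#' @param k number of features to return (default 5); truncated with a
#'   warning if larger than J.
#' @return integer vector of feature indices in decreasing order of
#'   `w[, component]`, ties broken by feature index.
#' @export
top_genes <- function(W, component, k = 5) {
  W <- as.matrix(W)
  if (component < 1 || component > ncol(W)) stop("invalid component index")
  if (k > nrow(W)) {
    warning("k exceeds the number of features; truncating to ", nrow(W))
    k <- nrow(W)
  }
  ord <- order(-W[, component], seq_len(nrow(W)))
  ord[seq_len(k)]
}
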