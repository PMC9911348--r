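#' Write a count dataset (and optional simulation truth) to a directory
#'
#' Counts are written as Matrix Market (`counts.mtx`, 1-based indices per
#' the format standard), observations (coordinates, size factors, optional
#' train mask) as `obs.tsv`, features as `features.tsv`, truth matrices as
#' CSV, and a JSON metadata sidecar recording the constants.
#'
#' @param data a [count_dataset()].
#' @param dir output directory (created if missing).
#' @param truth optional [simulation_truth()].
#' @param metadata optional named list merged into `metadata.json`.
#' @return invisibly, the directory path.
#' @export
write_dataset <- function(data, dir, truth = NULL, metadata = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Ysp <- methods::as(methods::as(Matrix::Matrix(as.matrix(data$Y), sparse = TRUE),
                                 "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(Ysp, file.path(dir, "counts.mtx"))
  obs <- data.frame(data$X, nu = data$nu)
  if (!is.null(data$train_mask)) obs$train <- data$train_mask
  utils::write.table(obs, file.path(dir, "obs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(feature_id = data$feature_ids),
                     file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    wr <- function(m, f) if (!is.null(m)) {
      utils::write.csv(as.data.frame(m), file.path(dir, f), row.names = FALSE)
    }
    wr(truth$F, "truth_F.csv"); wr(truth$H, "truth_H.csv")
    wr(truth$W, "truth_W.csv"); wr(truth$V, "truth_V.csv")
    wr(data.frame(score = truth$true_gene_scores), "truth_gene_scores.csv")
    metadata$truth_seed <- truth$seed
  }
  metadata$n_obs <- nrow(data$Y)
  metadata$n_features <- ncol(data$Y)
  jsonlite::write_json(metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a count dataset from a Matrix Market + TSV bundle
#'
#' Inverse of [write_dataset()]; round-trips `Y`, `X`, `nu`, feature ids
#' and the train mask exactly. Duplicate coordinates are permitted
#' (multiple cells per location).
#'
#' @param dir directory containing `counts.mtx`, `obs.tsv`, `features.tsv`.
#' @return a [count_dataset()].
#' @export
read_dataset <- function(dir) {
  fmtx <- file.path(dir, "counts.mtx")
  fobs <- file.path(dir, "obs.tsv")
  if (!file.exists(fmtx)) stop("missing counts.mtx in ", dir)
  if (!file.exists(fobs)) stop("missing obs.tsv (coordinates) in ", dir)
  Y <- as.matrix(Matrix::readMM(fmtx))
  if (any(Y != round(Y))) {
    stop("counts.mtx contains non-integer values; factor models expect raw ",
         "counts (normalize downstream, not upstream)")
  }
  obs <- utils::read.delim(fobs)
  coord_cols <- setdiff(names(obs), c("nu", "train"))
  if (length(coord_cols) < 1) stop("obs.tsv contains no coordinate columns")
  feat <- utils::read.delim(file.path(dir, "features.tsv"))
  count_dataset(
    Y = Y,
    X = as.matrix(obs[, coord_cols, drop = FALSE]),
    nu = if ("nu" %in% names(obs)) obs$nu else NULL,
    feature_ids = as.character(feat$feature_id),
    train_mask = if ("train" %in% names(obs)) obs$train else NULL
  )
}

#' Serialize a fitted model to a JSON bundle
#'
#' All parameters, the inducing locations and the coordinate transform are
#' written as a single schema-versioned JSON file; [load_model()] restores
#' a model usable for prediction and postprocessing. The training-data
#' cache (counts, precomputed cross-covariances) is rebuilt at load time
#' from the saved dataset when needed, so checkpoints stay small.
#'
#' @param model a `factor_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_model <- function(model, path) {
  obj <- list(
    schema_version = 1L,
    family = model$family, L = model$L, T = model$T, Lns = model$Lns,
    likelihood = model$likelihood, nonneg = model$nonneg,
    kernel = model$kernel, lengthscale = model$lengthscale,
    jitter = model$jitter,
    params = model$params,
    Z = model$cache$Z,
    transform = model$cache$transform,
    centering_means = model$cache$centering_means,
    median_total = model$cache$median_total,
    dims = list(N = model$cache$N, J = model$cache$J, M = model$cache$M,
                D = model$cache$D)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model saved with [save_model()]
#'
#' @param path JSON checkpoint path.
#' @param data optional [count_dataset()] (the training data) to rebuild
#'   the fitting cache; without it the model supports prediction and
#'   loadings access but not further fitting or `model_factors()`.
#' @return a `factor_model`.
#' @export
load_model <- function(path, data = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1) {
    stop("unsupported checkpoint schema")
  }
  dims <- obj$dims
  P <- obj$params
  fix <- function(x, dm) { x <- as.numeric(unlist(x)); dim(x) <- dm; x }
  Tn <- obj$T; Lns <- obj$Lns
  P$Wu <- fix(P$Wu, c(dims$J, Tn)); P$Vu <- fix(P$Vu, c(dims$J, Lns))
  P$beta1 <- fix(P$beta1, c(dims$D, Tn))
  P$Qmu <- fix(P$Qmu, c(dims$M, Tn))
  P$Qs <- fix(P$Qs, c(dims$M, dims$M, Tn))
  P$Hm <- fix(P$Hm, c(dims$N, Lns)); P$Hls <- fix(P$Hls, c(dims$N, Lns))
  P$log_a <- as.numeric(P$log_a); P$beta0 <- as.numeric(P$beta0)
  P$m <- as.numeric(P$m); P$log_s <- as.numeric(P$log_s)
  model <- structure(
    list(family = obj$family, L = obj$L, T = Tn, Lns = Lns,
         likelihood = obj$likelihood, nonneg = obj$nonneg,
         kernel = obj$kernel, lengthscale = obj$lengthscale,
         jitter = obj$jitter, params = P,
         cache = list(Z = if (!is.null(obj$Z)) as.matrix(obj$Z) else NULL,
                      transform = list(mins = as.numeric(obj$transform$mins),
                                       span = obj$transform$span),
                      centering_means = obj$centering_means,
                      median_total = obj$median_total,
                      N = dims$N, J = dims$J, M = dims$M, D = dims$D)),
    class = "factor_model"
  )
  if (!is.null(data)) {
    rebuilt <- new_factor_model(data, family = model$family, L = model$L,
                                T = if (model$family == "nsfh") model$T else NULL,
                                likelihood = if (model$nonneg) model$likelihood else NULL,
                                kernel = model$kernel,
                                M = model$cache$M,
                                ip_strategy = "all",
                                lengthscale = model$lengthscale)
    rebuilt$params <- model$params
    rebuilt$cache$Z <- model$cache$Z
    unit <- kernel_spec(model$kernel, 1, model$lengthscale)
    Kzz <- kernel_matrix(model$cache$Z, model$cache$Z, unit)
    rebuilt$cache$Ltri <- .chol_jitter(Kzz, 1, c(model$jitter, 1e-4, 1e-2))
    rebuilt$cache$Atilde <- forwardsolve(
      rebuilt$cache$Ltri, kernel_matrix(model$cache$Z, rebuilt$cache$Xs, unit))
    rebuilt$cache$ctilde <- pmax(1 - colSums(rebuilt$cache$Atilde^2), 1e-10)
    rebuilt$cache$M <- nrow(model$cache$Z)
    model <- rebuilt
  }
  model
}

#' Write fitted-model outputs with a hashed manifest
#'
#' Writes factors, loadings and scores as CSV, metrics and configuration
#' as JSON, plus `manifest.json` listing every artifact with its MD5
#' hash. Missing optional pieces are marked absent in the manifest rather
#' than failing.
#'
#' @param fit a [fit_model()] result (or `NULL`).
#' @param post a `simplex_factorization` (or `NULL`).
#' @param metrics named list of metric values (or `NULL`).
#' @param out_dir output directory.
#' @param config optional configuration list copied next to the outputs.
#' @return invisibly, the manifest as a named list.
#' @export
write_results <- function(fit = NULL, post = NULL, metrics = NULL, out_dir,
                          config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  add <- function(path) written <<- c(written, path)

  if (!is.null(fit)) {
    save_model(fit$model, file.path(out_dir, "model.json")); add("model.json")
    utils::write.csv(fit$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE); add("trace.csv")
    fac <- model_factors(fit$model)
    utils::write.csv(as.data.frame(cbind(fac$F, fac$H)),
                     file.path(out_dir, "factors.csv"), row.names = FALSE)
    add("factors.csv")
    utils::write.csv(as.data.frame(cbind(fac$W, fac$V)),
                     file.path(out_dir, "loadings.csv"), row.names = FALSE)
    add("loadings.csv")
  }
  if (!is.null(post)) {
    utils::write.csv(as.data.frame(post$F),
                     file.path(out_dir, "factors_simplex.csv"),
                     row.names = FALSE); add("factors_simplex.csv")
    utils::write.csv(as.data.frame(post$W),
                     file.path(out_dir, "loadings_simplex.csv"),
                     row.names = FALSE); add("loadings_simplex.csv")
    sc <- if (post$style == "spde") post$w_bar else post$f_bar
    utils::write.csv(data.frame(scaling = sc),
                     file.path(out_dir, "scaling.csv"), row.names = FALSE)
    add("scaling.csv")
  }
  if (!is.null(metrics)) {
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA); add("metrics.json")
  }
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA); add("config.json")
  }
  manifest <- list(
    artifacts = lapply(written, function(f) {
      list(file = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }),
    absent = setdiff(c("model.json", "trace.csv", "factors.csv",
                       "loadings.csv", "factors_simplex.csv",
                       "loadings_simplex.csv", "scaling.csv", "metrics.json",
                       "config.json"), written)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
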