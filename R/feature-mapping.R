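#' Map image features to embedding dimensions by ridge regression
#'
#' One ridge model per embedding dimension, evaluated by a leave-one-material
#' -out outer loop (all exemplars of one class held out together, preventing
#' exemplar leakage) with nested cross-validation over the penalty grid on
#' the remaining classes. Features are standardized and an intercept is
#' included; standardization statistics come from the training fold only.
#' Ridge solutions are computed in closed form from the SVD of the
#' standardized training matrix, which evaluates the whole penalty grid at
#' the cost of one decomposition.
#'
#' @param features `n_images x n_features` matrix (image ids as rownames).
#' @param embedding `n_images x n_dims` target matrix (same ids).
#' @param images Image metadata with `class_label` (defines the outer folds).
#' @param lambda_grid Penalties; default logarithmic over 8 decades.
#' @param inner_folds Inner CV folds over training classes (default 5).
#' @param seed Integer seed for the inner fold assignment.
#' @return A `ridge_map` list: `predictions` (held-out, assembled over outer
#'   folds, clipped at 0), `per_dim_r`, `chosen_lambda` (per dimension, from
#'   inner CV on the full training set, reused for novel images), `final`
#'   (full-data models for [predict_dimensions()]), `cv_table`.
#' @export
fit_ridge_maps <- function(features, embedding, images,
                           lambda_grid = 10^seq(-4, 3, length.out = 15),
                           inner_folds = 5, seed = 1) {
  ids <- intersect(rownames(features), rownames(embedding))
  stopifnot(length(ids) == nrow(features))
  X <- features[ids, , drop = FALSE]
  Y <- embedding[ids, , drop = FALSE]
  cl <- images$class_label[match(ids, images$image_id)]
  classes <- unique(cl)
  if (length(classes) < 3) stop("need at least 3 classes for the outer loop")
  if (length(lambda_grid) == 1)
    warning("single-penalty grid: inner CV is degenerate, using lambda = ",
            lambda_grid)
  set.seed(seed)
  inner_of_class <- setNames(
    sample(rep_len(seq_len(min(inner_folds, length(classes) - 1)),
                   length(classes))), classes)

  preds <- matrix(NA_real_, nrow(X), ncol(Y), dimnames = dimnames(Y))
  for (hold in classes) {
    te <- cl == hold
    tr <- !te
    lam <- .inner_cv_lambda(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                            inner_of_class[cl[tr]], lambda_grid)
    for (d in seq_len(ncol(Y))) {
      fit <- .ridge_fit(X[tr, , drop = FALSE], Y[tr, d], lam[d])
      preds[te, d] <- .ridge_predict(fit, X[te, , drop = FALSE])
    }
  }
  preds <- pmax(preds, 0)
  per_dim_r <- vapply(seq_len(ncol(Y)), function(d) {
    if (sd(preds[, d]) == 0 || sd(Y[, d]) == 0) 0 else cor(preds[, d], Y[, d])
  }, numeric(1))

  # penalty for novel images: inner CV on the full training set
  lam_full <- .inner_cv_lambda(X, Y, inner_of_class[cl], lambda_grid)
  final <- lapply(seq_len(ncol(Y)), function(d)
    .ridge_fit(X, Y[, d], lam_full[d]))
  structure(list(predictions = preds, per_dim_r = per_dim_r,
                 chosen_lambda = lam_full, final = final,
                 lambda_grid = lambda_grid,
                 dim_names = colnames(Y)), class = "ridge_map")
}

# inner CV (folds over classes): per-dimension lambda minimizing MSE
.inner_cv_lambda <- function(X, Y, fold, lambda_grid) {
  Y <- as.matrix(Y)
  nf <- length(unique(fold))
  err <- array(0, c(length(lambda_grid), ncol(Y)))
  for (f in unique(fold)) {
    tr <- fold != f
    sv <- .ridge_svd(X[tr, , drop = FALSE])
    for (d in seq_len(ncol(Y))) {
      for (li in seq_along(lambda_grid)) {
        fit <- .ridge_from_svd(sv, Y[tr, d], lambda_grid[li])
        p <- .ridge_predict(fit, X[!tr, , drop = FALSE])
        err[li, d] <- err[li, d] + mean((p - Y[!tr, d])^2)
      }
    }
  }
  lambda_grid[apply(err, 2, which.min)]
}

.ridge_svd <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  list(svd = svd(Xs), mu = mu, sg = sg)
}

.ridge_from_svd <- function(sv, y, lambda) {
  ybar <- mean(y)
  s <- sv$svd
  d <- s$d
  rhs <- crossprod(s$u, y - ybar)            # U' y
  shrink <- ifelse(d^2 + lambda > 0, d / (d^2 + lambda), 0)
  beta_s <- s$v %*% (rhs * shrink)
  list(beta = beta_s / sv$sg, intercept = ybar - sum(beta_s * sv$mu / sv$sg),
       lambda = lambda)
}

.ridge_fit <- function(X, y, lambda) .ridge_from_svd(.ridge_svd(X), y, lambda)

.ridge_predict <- function(fit, Xnew) {
  drop(Xnew %*% fit$beta) + fit$intercept
}

#' Predict embedding dimensions for (novel) images from features
#'
#' Applies the full-data per-dimension ridge models (penalties chosen on the
#' training set) to new feature rows; predictions are clipped at zero to
#' honor the nonnegativity of the embedding.
#'
#' @param ridge_map A `ridge_map` from [fit_ridge_maps()].
#' @param features_new `n_new x n_features` matrix (image ids as rownames).
#' @return Predicted embedding rows (`n_new x n_dims`, nonnegative).
#' @export
predict_dimensions <- function(ridge_map, features_new) {
  out <- vapply(ridge_map$final, function(fit)
    .ridge_predict(fit, features_new), numeric(nrow(features_new)))
  out <- matrix(pmax(out, 0), nrow(features_new),
                dimnames = list(rownames(features_new),
                                ridge_map$dim_names))
  out
}

#' Similarity matrix from predicted dimensions
#'
#' Synthesizes similarity judgments for (novel) images by running the exact
#' context marginalization on the feature-predicted embedding rows.
#'
#' @param predicted Predicted embedding (`n x k`, nonnegative).
#' @param ... Passed to [marginal_similarity()].
#' @return A `similarity_matrix`.
#' @export
synthetic_similarity <- function(predicted, ...) {
  marginal_similarity(predicted, ...)
}
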