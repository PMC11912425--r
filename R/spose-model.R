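#' Predicted 2-AFC choice probability
#'
#' Under the sparse positive similarity embedding, the probability that a
#' participant chooses option A over option B as more similar to the reference
#' is a softmax over the reference-option dot products:
#' \deqn{p(A) = \frac{e^{x_r \cdot x_a}}{e^{x_r \cdot x_a} + e^{x_r \cdot x_b}}}
#' i.e. logistic in the dot-product difference.
#'
#' @param embedding Nonnegative weight matrix with image ids as rownames.
#' @param reference,option_a,option_b Image ids (vectors of equal length are
#'   evaluated elementwise).
#' @return Probability (vector) of choosing option A, in `(0, 1)`.
#' @export
choice_probability <- function(embedding, reference, option_a, option_b) {
  ids <- rownames(embedding)
  idx <- function(x) {
    i <- match(x, ids)
    if (anyNA(i)) stop("image id not in embedding: ",
                       paste(unique(x[is.na(i)]), collapse = ", "))
    i
  }
  r <- idx(reference); a <- idx(option_a); b <- idx(option_b)
  if (any(r == a | r == b | a == b))
    stop("reference and options must be pairwise distinct")
  sa <- rowSums(embedding[r, , drop = FALSE] * embedding[a, , drop = FALSE])
  sb <- rowSums(embedding[r, , drop = FALSE] * embedding[b, , drop = FALSE])
  unname(.sigmoid(sa - sb))
}

#' Configuration for fitting the embedding
#'
#' @param n_init_dims Number of randomly initialized dimensions (the canonical
#'   full-scale fit uses 90).
#' @param lambda L1 penalty weight on the mean absolute weight (the canonical
#'   full-scale fit selected 0.0038 by cross-validation; retune for other
#'   datasets via [select_lambda()]).
#' @param train_fraction Fraction of trials used for training; the remainder
#'   is the held-out test set (default 0.9).
#' @param lambda_grid Candidate penalties for [select_lambda()].
#' @param n_cv_folds Folds for [select_lambda()] (default 5).
#' @param learning_rate,batch_size,max_epochs,patience Adam optimizer
#'   settings; `patience` is epochs without validation improvement before
#'   early stopping.
#' @param val_fraction Fraction of the training split held out within
#'   training for early stopping (default 0.1).
#' @param seed Integer seed controlling initialization, splits and shuffling.
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_init_dims = 90, lambda = 0.0038,
                       train_fraction = 0.9,
                       lambda_grid = 10^seq(-4, -1, length.out = 7),
                       n_cv_folds = 5,
                       learning_rate = 0.015, batch_size = 256,
                       max_epochs = 250, patience = 15,
                       val_fraction = 0.1, seed = 42) {
  stopifnot(train_fraction > 0, train_fraction < 1, lambda >= 0,
            n_init_dims >= 1)
  structure(list(n_init_dims = n_init_dims, lambda = lambda,
                 train_fraction = train_fraction, lambda_grid = lambda_grid,
                 n_cv_folds = n_cv_folds, learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "fit_config")
}

# trials -> 0-based index arrays + 0/1 choice for the C++ core
.encode_trials <- function(trials, ids) {
  r <- match(trials$reference, ids)
  a <- match(trials$option_a, ids)
  b <- match(trials$option_b, ids)
  if (anyNA(r) || anyNA(a) || anyNA(b))
    stop("trial references an image id missing from the image table")
  list(ref = r - 1L, oa = a - 1L, ob = b - 1L,
       ya = as.integer(trials$choice == "A"))
}

#' Fit a sparse positive similarity embedding to triplet choices
#'
#' Minimizes the mean cross-entropy of the observed 2-AFC choices under
#' [choice_probability()] plus `lambda` times the mean absolute weight,
#' subject to weight nonnegativity, by minibatch Adam with projection onto
#' the nonnegative orthant after every step. Initialization is half-normal
#' (absolute standard Gaussian) entries. Trials are split (seeded) into
#' train / held-out test by trial; a slice of the training split is used for
#' early stopping. Deterministic given `config$seed`.
#'
#' @param trials QC-passed trial `data.frame`.
#' @param images Image metadata (`image_id`; defines the embedding rows).
#' @param config A [fit_config()].
#' @return A `fit_result` list: `embedding` (nonnegative matrix, pruned and
#'   ordered via [prune_dimensions()] / [order_dimensions()] by the caller or
#'   [fit_and_prune()]), `raw_embedding`, `test_accuracy`, `test_logloss`,
#'   `train_loss`, `val_loss`, `val_acc` traces, `best_epoch`, `config`.
#' @export
fit_embedding <- function(trials, images, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  ids <- images$image_id
  n <- length(ids)
  nt <- nrow(trials)
  if (nt < 2) stop("need at least 2 trials to form train/test splits")
  set.seed(config$seed)
  W0 <- matrix(abs(rnorm(n * config$n_init_dims)), n, config$n_init_dims)

  perm <- sample.int(nt)
  n_train <- max(1L, floor(config$train_fraction * nt))
  tr_idx <- perm[seq_len(n_train)]
  te_idx <- perm[-seq_len(n_train)]
  n_val <- max(1L, floor(config$val_fraction * n_train))
  va_idx <- tr_idx[seq_len(n_val)]
  tr_idx <- tr_idx[-seq_len(n_val)]

  enc <- .encode_trials(trials, ids)
  sub <- function(i) lapply(enc, `[`, i)
  tr <- sub(tr_idx); va <- sub(va_idx); te <- sub(te_idx)

  sampled <- tabulate(c(enc$ref, enc$oa, enc$ob) + 1L, nbins = n)
  if (any(sampled == 0))
    warning("image(s) never sampled in any trial stay near zero: ",
            paste(ids[sampled == 0], collapse = ", "))

  fit <- sgd_fit_core(W0, tr$ref, tr$oa, tr$ob, tr$ya,
                      va$ref, va$oa, va$ob, va$ya,
                      lambda = config$lambda, lr = config$learning_rate,
                      batch_size = config$batch_size,
                      max_epochs = config$max_epochs,
                      patience = config$patience,
                      seed = .child_seed(config$seed, 1L),
                      adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8)
  W <- fit$weights
  rownames(W) <- ids
  colnames(W) <- sprintf("dim%d", seq_len(ncol(W)))

  test_acc <- test_ll <- NA_real_
  if (length(te_idx) > 0) {
    p <- .choice_prob_idx(W, te$ref + 1L, te$oa + 1L, te$ob + 1L)
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    test_ll <- -mean(te$ya * log(pc) + (1 - te$ya) * log(1 - pc))
    test_acc <- mean((p >= 0.5) == (te$ya == 1))
  }
  structure(list(embedding = W, raw_embedding = W,
                 test_accuracy = test_acc, test_logloss = test_ll,
                 train_loss = fit$train_loss, val_loss = fit$val_loss,
                 val_acc = fit$val_acc, best_epoch = fit$best_epoch,
                 n_epochs = fit$n_epochs, config = config),
            class = "fit_result")
}

.choice_prob_idx <- function(W, r, a, b) {
  sa <- rowSums(W[r, , drop = FALSE] * W[a, , drop = FALSE])
  sb <- rowSums(W[r, , drop = FALSE] * W[b, , drop = FALSE])
  .sigmoid(sa - sb)
}

#' Fit, prune and order in one call
#'
#' Convenience wrapper: [fit_embedding()], then [prune_dimensions()] with
#' `prune_tol`, then [order_dimensions()].
#'
#' @inheritParams fit_embedding
#' @param prune_tol Relative pruning tolerance (see [prune_dimensions()]).
#' @return The `fit_result` with `embedding` pruned/ordered and `n_pruned`
#'   added.
#' @export
fit_and_prune <- function(trials, images, config = fit_config(),
                          prune_tol = 0.1) {
  res <- fit_embedding(trials, images, config)
  pr <- prune_dimensions(res$embedding, tol = prune_tol)
  res$embedding <- order_dimensions(pr$embedding)
  res$n_pruned <- pr$n_pruned
  res
}

#' Select the L1 penalty by cross-validation
#'
#' K-fold cross-validation over `config$lambda_grid` on the training split:
#' for each fold and candidate penalty the model is refit and scored by
#' held-out fold accuracy. Returns the penalty maximizing mean validation
#' accuracy; ties go to the larger (sparser) penalty.
#'
#' @param trials Trial `data.frame`.
#' @param images Image metadata.
#' @param config A [fit_config()]; `lambda_grid` and `n_cv_folds` are used,
#'   and each CV fit runs with the same optimizer settings.
#' @return A list with `lambda` (chosen value) and `cv_table` (data.frame:
#'   lambda, mean/sd of fold accuracy and logloss).
#' @export
select_lambda <- function(trials, images, config = fit_config()) {
  grid <- sort(config$lambda_grid)
  if (length(grid) == 0) stop("lambda_grid is empty")
  nt <- nrow(trials)
  set.seed(.child_seed(config$seed, 2L))
  fold <- sample(rep_len(seq_len(config$n_cv_folds), nt))
  acc <- ll <- matrix(NA_real_, length(grid), config$n_cv_folds)
  enc <- .encode_trials(trials, images$image_id)
  for (gi in seq_along(grid)) {
    for (f in seq_len(config$n_cv_folds)) {
      cfg <- config
      cfg$lambda <- grid[gi]
      cfg$train_fraction <- 0.999  # fold split handled here, not inside
      cfg$seed <- .child_seed(config$seed, 100L + f)
      fit <- tryCatch(
        fit_embedding(trials[fold != f, , drop = FALSE], images, cfg),
        error = function(e) e)
      if (inherits(fit, "error")) next
      hold <- lapply(enc, `[`, fold == f)
      p <- .choice_prob_idx(fit$embedding, hold$ref + 1L, hold$oa + 1L,
                            hold$ob + 1L)
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      acc[gi, f] <- mean((p >= 0.5) == (hold$ya == 1))
      ll[gi, f] <- -mean(hold$ya * log(pc) + (1 - hold$ya) * log(1 - pc))
    }
  }
  if (all(is.na(acc)))
    stop("all cross-validation fits failed for lambda grid: ",
         paste(signif(grid, 3), collapse = ", "))
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  best <- max(which(mean_acc >= max(mean_acc) - 1e-12))  # tie -> larger lambda
  list(lambda = grid[best],
       cv_table = data.frame(lambda = grid, mean_accuracy = mean_acc,
                             sd_accuracy = apply(acc, 1, sd, na.rm = TRUE),
                             mean_logloss = rowMeans(ll, na.rm = TRUE)))
}

#' Prune near-zero dimensions
#'
#' Drops every dimension whose maximum weight across images falls below the
#' tolerance. `tol` is interpreted relative to the global maximum weight
#' (default: drop dimensions whose peak is under 10% of the overall peak);
#' set `relative = FALSE` for an absolute threshold.
#'
#' @param embedding Nonnegative weight matrix.
#' @param tol Positive tolerance.
#' @param relative Interpret `tol` as a fraction of `max(embedding)`.
#' @return A list with the pruned `embedding` (columns re-indexed) and
#'   `n_pruned`.
#' @export
prune_dimensions <- function(embedding, tol = 0.1, relative = TRUE) {
  stopifnot(tol > 0)
  thr <- if (relative) tol * max(embedding) else tol
  peak <- apply(embedding, 2, max)
  keep <- peak > 0 & peak >= thr
  out <- embedding[, keep, drop = FALSE]
  if (ncol(out) > 0) colnames(out) <- sprintf("dim%d", seq_len(ncol(out)))
  list(embedding = out, n_pruned = sum(!keep))
}

#' Order dimensions by descending mean weight
#'
#' Columns are permuted by the mean weight across images, in descending
#' order, with a stable tie-break on the original column index.
#'
#' @param embedding Nonnegative weight matrix.
#' @return The column-permuted embedding, renamed `dim1..dimK`.
#' @export
order_dimensions <- function(embedding) {
  if (ncol(embedding) == 0) return(embedding)
  m <- colMeans(embedding)
  ord <- order(-m, seq_along(m))
  out <- embedding[, ord, drop = FALSE]
  colnames(out) <- sprintf("dim%d", seq_len(ncol(out)))
  out
}

#' Write / read an embedding as TSV with a JSON sidecar
#'
#' The TSV has `image_id` as its first column and `dim1..dimK` after; the
#' sidecar (`<path>.json`) records the fit configuration and metrics.
#'
#' @param result A `fit_result`, or a bare embedding matrix.
#' @param path Output TSV path.
#' @export
write_embedding <- function(result, path) {
  W <- if (inherits(result, "fit_result")) result$embedding else result
  df <- data.frame(image_id = rownames(W), W, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (inherits(result, "fit_result")) {
    meta <- list(config = unclass(result$config),
                 test_accuracy = result$test_accuracy,
                 test_logloss = result$test_logloss,
                 n_pruned = result$n_pruned,
                 best_epoch = result$best_epoch)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_embedding
#' @return `read_embedding`: the weight matrix with image ids as rownames.
#' @export
read_embedding <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df$image_id
  W
}
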