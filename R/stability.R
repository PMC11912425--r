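#' Dimension reproducibility across random restarts
#'
#' For every dimension of the reference embedding and every restarted fit,
#' finds the run dimension with the maximal Pearson correlation across shared
#' images (greedy best match per reference dimension: two reference
#' dimensions may match the same run dimension). Per-run correlations are
#' averaged after Fisher z-transformation (r clamped at `1 - 1e-7` before
#' the transform) and back-transformed to a per-dimension reproducibility.
#'
#' @param reference Reference embedding (matrix, image ids as rownames).
#' @param runs List of embeddings from independent refits.
#' @param method `"greedy"` (best match per reference dimension, the default)
#'   or `"hungarian"` (one-to-one assignment).
#' @return A `data.frame`: `dimension`, `reproducibility`, and per-run best
#'   correlations `run1..runR`. Zero-variance dimensions are excluded with a
#'   warning.
#' @export
reproducibility <- function(reference, runs, method = c("greedy",
                                                        "hungarian")) {
  method <- match.arg(method)
  common <- Reduce(intersect, c(list(rownames(reference)),
                                lapply(runs, rownames)))
  if (length(common) < 3) stop("fewer than 3 shared images across embeddings")
  ref <- reference[common, , drop = FALSE]
  keep <- apply(ref, 2, sd) > 0
  if (any(!keep)) {
    warning("zero-variance reference dimension(s) excluded: ",
            paste(which(!keep), collapse = ", "))
    ref <- ref[, keep, drop = FALSE]
  }
  kd <- ncol(ref)
  per_run <- vapply(runs, function(run) {
    run <- run[common, , drop = FALSE]
    ok <- apply(run, 2, sd) > 0
    run <- run[, ok, drop = FALSE]
    cm <- cor(ref, run)
    if (method == "greedy") {
      apply(cm, 1, max)
    } else {
      # Hungarian assignment on negated correlations; when the run has
      # fewer dimensions than the reference, unmatchable reference
      # dimensions are assigned to padded dummies and reported as NA
      cost <- max(cm) - cm
      if (nrow(cost) > ncol(cost))
        cost <- cbind(cost, matrix(max(cost) + 1, nrow(cost),
                                   nrow(cost) - ncol(cost)))
      idx <- .hungarian(cost)
      r <- ifelse(idx <= ncol(cm), cm[cbind(seq_len(kd), idx)], NA_real_)
      r
    }
  }, numeric(kd))
  per_run <- matrix(per_run, nrow = kd)
  z <- atanh(pmin(pmax(per_run, -1 + 1e-7), 1 - 1e-7))
  out <- data.frame(dimension = which(keep),
                    reproducibility = tanh(rowMeans(z)))
  colnames_runs <- sprintf("run%d", seq_along(runs))
  out[colnames_runs] <- as.data.frame(per_run)
  out
}

# Hungarian algorithm via iterative augmenting paths (small matrices only)
.hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1); p <- integer(m + 1)
  way <- integer(m + 1)
  INF <- .Machine$double.xmax / 4
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(INF, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) { u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Stability of dimensions under category removal
#'
#' Removes whole material classes (a random fraction, or a named list), drops
#' every image of those classes and every trial touching them, refits the
#' embedding `n_runs` times with seeds derived from `seed` by fixed offsets,
#' and matches each reference dimension against each refit on the retained
#' images.
#'
#' @param trials Trial `data.frame`.
#' @param images Image metadata.
#' @param reference Reference embedding fit on the full data.
#' @param config A [fit_config()] for the refits.
#' @param removal Either a fraction of classes to remove at random, or a
#'   character vector of class labels (targeted removal).
#' @param n_runs Number of refits (default 5; the canonical analysis uses
#'   50).
#' @param prune_tol Pruning tolerance passed to [fit_and_prune()].
#' @param seed Master seed; restart seeds are derived by fixed offsets.
#' @return A list: `table` (per-dimension reproducibility vs the reference),
#'   `mean_reproducibility`, `removed_classes`, `trial_removal_fraction`.
#' @export
subset_stability <- function(trials, images, reference, config,
                             removal = 0.18, n_runs = 5, prune_tol = 0.1,
                             seed = 1) {
  classes <- unique(images$class_label)
  if (is.numeric(removal)) {
    stopifnot(removal >= 0, removal < 1)
    set.seed(.child_seed(seed, 3L))
    removed <- sample(classes, round(removal * length(classes)))
  } else {
    stopifnot(all(removal %in% classes))
    removed <- removal
  }
  drop_ids <- images$image_id[images$class_label %in% removed]
  keep_img <- !(images$image_id %in% drop_ids)
  touched <- trials$reference %in% drop_ids |
    trials$option_a %in% drop_ids | trials$option_b %in% drop_ids
  frac_removed <- mean(touched)
  sub_tr <- trials[!touched, , drop = FALSE]
  sub_img <- images[keep_img, , drop = FALSE]
  runs <- lapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- .child_seed(seed, 10L + r)
    fit_and_prune(sub_tr, sub_img, cfg, prune_tol = prune_tol)$embedding
  })
  tab <- reproducibility(reference, runs)
  list(table = tab, mean_reproducibility = mean(tab$reproducibility),
       removed_classes = removed, trial_removal_fraction = frac_removed,
       n_runs = n_runs)
}
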