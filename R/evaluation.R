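#' Intersubject consistency ceiling from repeated triplets
#'
#' Groups trials by unique triplet (reference plus unordered option pair; the
#' `repeat_block` tag is used when present) and computes, per triplet, the
#' modal-response fraction `max(c_A, c_B) / m` over its `m` responses. The
#' ceiling is 100 times the mean over triplets, the best single-trial
#' accuracy any pooled-participant model can reach given response variance.
#'
#' @param repeats Trial `data.frame`; triplets with fewer than 2 responses
#'   are dropped.
#' @return Ceiling percentage, with attribute `n_triplets`.
#' @export
consistency_ceiling <- function(repeats) {
  dt <- data.table::as.data.table(repeats)
  if ("repeat_block" %in% names(dt)) {
    dt[, key := repeat_block]
  } else {
    dt[, key := paste(reference, pmin(option_a, option_b),
                      pmax(option_a, option_b))]
  }
  # count choices by option image (not by A/B slot, which can be swapped)
  dt[, chosen := ifelse(choice == "A", option_a, option_b)]
  per <- dt[, {
    tab <- table(chosen)
    list(m = .N, modal = max(tab) / .N)
  }, by = key]
  per <- per[per$m >= 2]
  if (nrow(per) == 0) stop("no triplet has >= 2 responses")
  structure(100 * mean(per$modal), n_triplets = nrow(per))
}

#' Chance-corrected accuracy
#'
#' `100 * (accuracy - chance) / (ceiling - chance)`: model accuracy rescaled
#' so 0 is chance and 100 is the intersubject consistency ceiling.
#'
#' @param accuracy_pct,ceiling_pct,chance_pct Percentages; `ceiling_pct` must
#'   exceed `chance_pct`.
#' @return Percentage.
#' @export
chance_corrected <- function(accuracy_pct, ceiling_pct, chance_pct = 50) {
  if (ceiling_pct <= chance_pct)
    stop("chance-corrected accuracy undefined: ceiling (", ceiling_pct,
         ") must exceed chance (", chance_pct, ")")
  100 * (accuracy_pct - chance_pct) / (ceiling_pct - chance_pct)
}

.lower_tri <- function(m) m[lower.tri(m)]

#' Compare two similarity matrices
#'
#' Pearson correlation over lower-triangle entries present in both matrices,
#' with a Mantel-style randomization test (item labels of `B` permuted
#' jointly over rows and columns) and a bootstrap-over-items confidence
#' interval.
#'
#' @param A,B `similarity_matrix` objects over the same image ids (matched by
#'   rowname when available).
#' @param n_perm Label permutations (default 10000).
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param seed Integer seed.
#' @return List with `r`, `ci` (2.5/97.5% bootstrap percentiles), `p`
#'   (permutation), `n_pairs`.
#' @export
compare_matrices <- function(A, B, n_perm = 10000, n_boot = 1000, seed = 1) {
  if (!is.null(rownames(A)) && !is.null(rownames(B))) {
    common <- intersect(rownames(A), rownames(B))
    A <- A[common, common]
    B <- B[common, common]
  }
  stopifnot(nrow(A) == nrow(B))
  n <- nrow(A)
  ok <- !is.na(A) & !is.na(B)
  lt <- lower.tri(A) & ok
  r_obs <- cor(A[lt], B[lt])
  set.seed(seed)
  r_perm <- replicate(n_perm, {
    p <- sample.int(n)
    Bp <- B[p, p]
    keep <- lower.tri(A) & !is.na(A) & !is.na(Bp)
    cor(A[keep], Bp[keep])
  })
  p_val <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1)
  r_boot <- replicate(n_boot, {
    idx <- sample.int(n, replace = TRUE)
    Ab <- A[idx, idx]; Bb <- B[idx, idx]
    same <- outer(idx, idx, "==")  # resampled duplicates of one item
    keep <- lower.tri(Ab) & !same & !is.na(Ab) & !is.na(Bb)
    if (sum(keep) < 3) NA_real_ else cor(Ab[keep], Bb[keep])
  })
  list(r = r_obs,
       ci = quantile(r_boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
       p = p_val, n_pairs = sum(lt))
}

#' Split-half reliability of a behavioral similarity matrix
#'
#' Trials are split randomly in half within each unique triplet cell; two
#' behavioral similarity matrices are built and their lower triangles
#' correlated. The half-matrix correlation, averaged over `n_splits` random
#' splits, is stepped up to full test length with the Spearman-Brown formula
#' `2 r / (1 + r)`.
#'
#' @param trials Trial `data.frame`.
#' @param images Image metadata.
#' @param n_splits Random splits to average (default 10).
#' @param seed Integer seed.
#' @return List with `r_corrected`, `r_half` (mean), `r_half_all` (per
#'   split).
#' @export
split_half_reliability <- function(trials, images, n_splits = 10, seed = 1) {
  set.seed(seed)
  key <- paste(trials$reference,
               pmin(trials$option_a, trials$option_b),
               pmax(trials$option_a, trials$option_b))
  rs <- vapply(seq_len(n_splits), function(s) {
    half <- logical(nrow(trials))
    for (ix in split(seq_len(nrow(trials)), key)) {
      h <- sample(ix, floor(length(ix) / 2))
      half[h] <- TRUE
    }
    m1 <- suppressWarnings(
      behavioral_similarity(trials[half, , drop = FALSE], images))
    m2 <- suppressWarnings(
      behavioral_similarity(trials[!half, , drop = FALSE], images))
    ok <- lower.tri(m1) & !is.na(m1) & !is.na(m2)
    cor(m1[ok], m2[ok])
  }, numeric(1))
  r_half <- mean(rs)
  list(r_corrected = spearman_brown(r_half), r_half = r_half,
       r_half_all = rs)
}

#' Spearman-Brown step-up
#' @param r Split-half correlation.
#' @return `2 r / (1 + r)`.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Explainable variance captured by the model
#'
#' The squared model-behavior matrix correlation expressed as a share of the
#' (Spearman-Brown corrected) reliability of the behavioral matrix:
#' `100 * model_r^2 / corrected_reliability`.
#'
#' @param model_r Model-to-behavior matrix correlation.
#' @param corrected_reliability Spearman-Brown corrected split-half
#'   reliability.
#' @return Percentage.
#' @export
explainable_variance <- function(model_r, corrected_reliability) {
  stopifnot(corrected_reliability > 0)
  100 * model_r^2 / corrected_reliability
}

#' Within- vs between-class similarity
#'
#' Per class: the mean similarity among its exemplars (within) and the mean
#' similarity of its exemplars to all images outside the class (between),
#' compared by a paired t test across classes (`df = n_classes - 1`).
#'
#' @param sim `similarity_matrix`.
#' @param images Image metadata with `class_label`.
#' @return List with `within_mean`, `between_mean`, `t`, `df`, `p`, and the
#'   per-class table. Degenerate (zero-variance) differences give `t = NaN`
#'   with a warning.
#' @export
within_between_class <- function(sim, images) {
  ids <- rownames(sim)
  cl <- images$class_label[match(ids, images$image_id)]
  classes <- unique(cl)
  per <- t(vapply(classes, function(c0) {
    inside <- which(cl == c0)
    outside <- which(cl != c0)
    wb <- sim[inside, inside, drop = FALSE]
    w <- if (length(inside) > 1) mean(.lower_tri(wb), na.rm = TRUE) else NA
    b <- mean(sim[inside, outside], na.rm = TRUE)
    c(within = w, between = b)
  }, numeric(2)))
  d <- per[, "within"] - per[, "between"]
  d <- d[!is.na(d)]
  n <- length(d)
  if (sd(d) == 0 || n < 2) {
    warning("degenerate within-between differences; t undefined")
    tval <- NaN; pval <- NaN
  } else {
    tval <- mean(d) / (sd(d) / sqrt(n))
    pval <- 2 * pt(-abs(tval), df = n - 1)
  }
  list(within_mean = mean(per[, "within"], na.rm = TRUE),
       between_mean = mean(per[, "between"], na.rm = TRUE),
       t = tval, df = n - 1, p = pval,
       per_class = data.frame(class_label = classes, per,
                              row.names = NULL))
}

#' Few-shot class decoding from the embedding
#'
#' Leave-one-exemplar-out linear SVM decoding of material class from the
#' embedding rows: per fold, the classifier trains on the other exemplars of
#' every class (2 per class in the canonical 3-exemplar design) and is
#' evaluated on the held-out exemplars. Top-k accuracy and the median rank of
#' the correct class come from one-vs-one voting of the multiclass linear
#' SVM; pairwise accuracy is the mean held-out accuracy over all class pairs
#' of dedicated 2-class SVMs.
#'
#' @param embedding Weight matrix, image ids as rownames.
#' @param images Image metadata with `class_label` and `exemplar_index`.
#' @param cost SVM cost parameter (default 1, logged in the result).
#' @return List with `pairwise_acc`, `top1`, `top5`, `median_rank` (all
#'   accuracies in percent), `cost`.
#' @export
decode_classes <- function(embedding, images, cost = 1) {
  ids <- rownames(embedding)
  meta <- images[match(ids, images$image_id), ]
  cl <- factor(meta$class_label)
  ex <- meta$exemplar_index
  folds <- sort(unique(ex))
  nc <- nlevels(cl)

  ranks <- integer(0)
  for (f in folds) {
    tr <- ex != f; te <- ex == f
    fit <- e1071::svm(embedding[tr, , drop = FALSE], cl[tr],
                      kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(stats::predict(fit, embedding[te, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    votes <- matrix(0, sum(te), nc, dimnames = list(NULL, levels(cl)))
    pairs <- strsplit(colnames(dv), "/")
    for (p in seq_along(pairs)) {
      win1 <- dv[, p] > 0
      votes[, pairs[[p]][1]] <- votes[, pairs[[p]][1]] + win1
      votes[, pairs[[p]][2]] <- votes[, pairs[[p]][2]] + !win1
    }
    true_i <- match(as.character(cl[te]), colnames(votes))
    for (i in seq_len(nrow(votes))) {
      # rank of the true class by votes (average rank under ties)
      rk <- rank(-votes[i, ], ties.method = "average")
      ranks <- c(ranks, rk[true_i[i]])
    }
  }
  top1 <- 100 * mean(ranks <= 1)
  top5 <- 100 * mean(ranks <= 5)

  # exhaustive pairwise 2-class decoding
  cls <- levels(cl)
  pair_acc <- numeric(0)
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      sel <- cl %in% c(cls[i], cls[j])
      y <- droplevels(cl[sel])
      X <- embedding[sel, , drop = FALSE]
      exs <- ex[sel]
      acc <- vapply(folds, function(f) {
        tr <- exs != f; te <- exs == f
        if (nlevels(droplevels(y[tr])) < 2 || !any(te)) return(NA_real_)
        fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                          cost = cost, scale = FALSE)
        mean(stats::predict(fit, X[te, , drop = FALSE]) == y[te])
      }, numeric(1))
      pair_acc <- c(pair_acc, mean(acc, na.rm = TRUE))
    }
  }
  list(pairwise_acc = 100 * mean(pair_acc), top1 = top1, top5 = top5,
       median_rank = stats::median(ranks), cost = cost)
}

#' Compare behavioral similarity with a semantic embedding
#'
#' Aggregates the similarity matrix to class level (mean of each exemplar
#' block per class pair), builds the semantic class-by-class matrix as the
#' Pearson correlations between the classes' semantic vectors, and reports
#' the squared Pearson correlation between the two lower triangles.
#'
#' @param sim `similarity_matrix` at image level.
#' @param images Image metadata with `class_label`.
#' @param semantic_vectors Class-by-dimension matrix, class labels as
#'   rownames; alternatively pass a precomputed class-by-class
#'   `semantic_matrix` instead.
#' @param semantic_matrix Optional precomputed semantic similarity matrix
#'   (class labels as dimnames), bypassing the correlation step.
#' @return List with `r_squared`, `r`, `n_classes`.
#' @export
semantic_comparison <- function(sim, images, semantic_vectors = NULL,
                                semantic_matrix = NULL) {
  ids <- rownames(sim)
  cl <- images$class_label[match(ids, images$image_id)]
  classes <- if (is.null(semantic_matrix)) rownames(semantic_vectors) else
    rownames(semantic_matrix)
  stopifnot(all(classes %in% cl))
  nc <- length(classes)
  beh <- matrix(NA_real_, nc, nc, dimnames = list(classes, classes))
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      beh[i, j] <- mean(sim[cl == classes[i], cl == classes[j]],
                        na.rm = TRUE)
    }
  }
  sem <- if (is.null(semantic_matrix)) cor(t(semantic_vectors)) else
    semantic_matrix[classes, classes]
  lt <- lower.tri(beh)
  r <- cor(beh[lt], sem[lt])
  list(r_squared = r^2, r = r, n_classes = nc)
}

#' Agreement between predicted and observed choice probabilities
#'
#' For a repeated-triplet set, compares the model's predicted probability of
#' each triplet's modal option-A choice with the observed choice frequency:
#' reports the Pearson correlation and an accuracy defined as 100 minus the
#' mean absolute deviation in percentage points (an interpretation of
#' probability-level predictive accuracy; both are returned so either can be
#' quoted).
#'
#' @param embedding Weight matrix.
#' @param repeats Repeated-triplet trial `data.frame`.
#' @return List with `r`, `accuracy_pct`, `n_triplets`.
#' @export
choice_prob_agreement <- function(embedding, repeats) {
  dt <- data.table::as.data.table(repeats)
  key <- if ("repeat_block" %in% names(dt)) dt$repeat_block else
    paste(dt$reference, pmin(dt$option_a, dt$option_b),
          pmax(dt$option_a, dt$option_b))
  dt[, grp := key]
  dt[, chose_a := choice == "A"]
  obs <- dt[, list(p_obs = mean(chose_a), reference = reference[1],
                   option_a = option_a[1], option_b = option_b[1]),
            by = grp]
  p_pred <- choice_probability(embedding, obs$reference, obs$option_a,
                               obs$option_b)
  list(r = cor(p_pred, obs$p_obs),
       accuracy_pct = 100 - mean(abs(p_pred - obs$p_obs)) * 100,
       n_triplets = nrow(obs))
}

#' Per-image dimension pruning curve
#'
#' Starting from the full embedding, repeatedly sets each image's smallest
#' nonzero weight to zero (simultaneously across images), recomputes the
#' predicted choice probabilities on a fixed evaluation triplet set, and
#' records the squared correlation with the full model's predictions. Returns
#' the curve indexed by the maximum number of dimensions retained per image
#' and the smallest per-image dimension count at which 95% and 99% of the
#' full model's predictive variance is preserved.
#'
#' @param embedding Weight matrix.
#' @param eval_triplets `data.frame` with `reference`, `option_a`,
#'   `option_b` columns (e.g. simulated trials).
#' @return List with `curve` (data.frame: dims_retained, r_squared),
#'   `dims_95`, `dims_99`.
#' @export
dimension_pruning_curve <- function(embedding, eval_triplets) {
  W <- embedding
  k <- ncol(W)
  ids <- rownames(W)
  enc <- list(r = match(eval_triplets$reference, ids),
              a = match(eval_triplets$option_a, ids),
              b = match(eval_triplets$option_b, ids))
  p_full <- .choice_prob_idx(W, enc$r, enc$a, enc$b)
  r2_of <- function(Wp) {
    p <- .choice_prob_idx(Wp, enc$r, enc$a, enc$b)
    if (sd(p) == 0 || sd(p_full) == 0) {
      if (max(abs(p - p_full)) < 1e-12) 1 else 0
    } else cor(p, p_full)^2
  }
  # curve is indexed by the realized per-image dimension budget
  Wp <- W
  dims <- max(rowSums(Wp > 0))
  curve <- data.frame(dims_retained = dims, r_squared = 1)
  while (max(rowSums(Wp > 0)) > 1) {
    for (i in seq_len(nrow(Wp))) {
      nz <- which(Wp[i, ] > 0)
      if (length(nz) > 1) Wp[i, nz[which.min(Wp[i, nz])]] <- 0
    }
    curve <- rbind(curve,
                   data.frame(dims_retained = max(rowSums(Wp > 0)),
                              r_squared = r2_of(Wp)))
  }
  thresh_at <- function(th) {
    ok <- curve$dims_retained[curve$r_squared >= th]
    if (length(ok)) min(ok) else NA_integer_
  }
  list(curve = curve, dims_95 = thresh_at(0.95), dims_99 = thresh_at(0.99))
}

#' Assemble a full evaluation report
#'
#' Runs the evaluation battery against a fitted embedding, a repeated-triplet
#' set and (optionally) a behavioral similarity matrix and semantic vectors,
#' returning one list that serializes cleanly to JSON.
#'
#' @param embedding Fitted weight matrix.
#' @param images Image metadata.
#' @param repeats Repeated-triplet trials for the ceiling.
#' @param model_accuracy_pct Held-out trial accuracy of the fit, percent.
#' @param behavioral Optional behavioral `similarity_matrix` to compare with
#'   the model's reconstruction.
#' @param semantic_vectors Optional class-level semantic matrix.
#' @param n_perm Permutations for [compare_matrices()].
#' @param seed Integer seed.
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(embedding, images, repeats,
                              model_accuracy_pct, behavioral = NULL,
                              semantic_vectors = NULL, n_perm = 1000,
                              seed = 1) {
  ceiling_pct <- as.numeric(consistency_ceiling(repeats))
  rep_list <- list(
    ceiling_pct = ceiling_pct,
    model_accuracy_pct = model_accuracy_pct,
    chance_corrected_pct = chance_corrected(model_accuracy_pct, ceiling_pct))
  sim_model <- marginal_similarity(embedding)
  wb <- within_between_class(sim_model, images)
  rep_list$within_mean <- wb$within_mean
  rep_list$between_mean <- wb$between_mean
  rep_list$within_between_t <- wb$t
  if (!is.null(behavioral)) {
    cmpr <- compare_matrices(sim_model, behavioral, n_perm = n_perm,
                             seed = seed)
    rep_list$matrix_r <- cmpr$r
    rep_list$matrix_ci <- cmpr$ci
    rep_list$matrix_p <- cmpr$p
  }
  if (!is.null(semantic_vectors))
    rep_list$semantic_r2 <- semantic_comparison(sim_model, images,
                                                semantic_vectors)$r_squared
  agree <- choice_prob_agreement(embedding, repeats)
  rep_list$choice_prob_r <- agree$r
  rep_list$choice_prob_accuracy_pct <- agree$accuracy_pct
  structure(rep_list, class = "evaluation_report")
}

utils::globalVariables(c("key", "repeat_block", "reference", "option_a",
                         "option_b", "choice", "chosen", "grp", "chose_a",
                         "m", "y", "p1", "p2", "ctx"))
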