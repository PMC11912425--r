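#' Number of trials in a fully sampled triplet design
#'
#' Each unordered 3-image context is presented once per reference assignment,
#' so a full pass over `n_images` items takes `3 * choose(n_images, 3)`
#' trials; the canonical 600-image set needs ~107.46 million, and the
#' fully-sampled 60-image subset with two repeats takes 205,320 responses.
#'
#' @param n_images Number of images (>= 3).
#' @param n_repeats Repeats of the full design (default 1).
#' @return Trial count (numeric to avoid integer overflow at scale).
#' @export
full_design_size <- function(n_images, n_repeats = 1) {
  stopifnot(n_images >= 3)
  n_repeats * 3 * choose(n_images, 3)
}

#' Fraction of a full design lost when images are removed
#'
#' When `m_images` images are deleted, every triplet touching any of them is
#' lost from the fully sampled design; the surviving fraction is
#' `choose(n - m, 3) / choose(n, 3)`.
#'
#' @param n_images Total images.
#' @param m_images Images removed.
#' @return Fraction of trials removed, in `[0, 1]`.
#' @export
design_removal_fraction <- function(n_images, m_images) {
  stopifnot(m_images >= 0, m_images <= n_images)
  if (n_images - m_images < 3) return(1)
  1 - choose(n_images - m_images, 3) / choose(n_images, 3)
}

#' Reconstruct the full similarity matrix from an embedding
#'
#' Defines the similarity of images i and j as the probability p(i,j) that
#' they end up as the (reference, chosen) pair, marginalized over every
#' possible context image k: for each context, the model's predicted
#' probability of choosing j when i is the reference (options j, k) and of
#' choosing i when j is the reference (options i, k) are averaged; p(i,j) is
#' the mean over the `n - 2` contexts. Exact mode enumerates all contexts
#' (vectorized; intended for up to ~700 images). Sampled mode draws contexts
#' with replacement and reports a Monte-Carlo standard error.
#'
#' By construction the three pair probabilities within one context sum to
#' 3/2, so the mean off-diagonal entry of the exact-mode matrix is 0.5 for
#' any embedding.
#'
#' @param embedding Nonnegative weight matrix, image ids as rownames.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_contexts Contexts per pair in sampled mode.
#' @param seed Seed for sampled mode.
#' @return A `similarity_matrix`: symmetric matrix in `[0, 1]` with unit
#'   diagonal (display convention; excluded from statistics). Sampled mode
#'   attaches attribute `mc_se` (mean Monte-Carlo standard error).
#' @export
marginal_similarity <- function(embedding, mode = c("exact", "sampled"),
                                n_contexts = 1000, seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(embedding)
  if (n < 3) stop("need at least 3 images")
  S <- tcrossprod(embedding)
  ids <- rownames(embedding)
  if (mode == "exact") {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      # entry [j, k] of P is P(choose j | ref = i, options {j, k})
      P <- .sigmoid(outer(S[i, ], S[i, ], "-"))
      rs <- rowSums(P)
      # remove infeasible contexts k = i and k = j (sigma(0) = 0.5)
      M[i, ] <- (rs - P[, i] - 0.5) / (n - 2)
    }
    sim <- (M + t(M)) / 2
  } else {
    set.seed(seed)
    sim <- matrix(0, n, n)
    se <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        k <- sample(setdiff(seq_len(n), c(i, j)), n_contexts, replace = TRUE)
        v <- (.sigmoid(S[i, j] - S[i, k]) + .sigmoid(S[j, i] - S[j, k])) / 2
        sim[i, j] <- sim[j, i] <- mean(v)
        se[i, j] <- se[j, i] <- sd(v) / sqrt(n_contexts)
      }
    }
  }
  diag(sim) <- 1
  dimnames(sim) <- list(ids, ids)
  out <- structure(sim, class = c("similarity_matrix", "matrix"))
  if (mode == "sampled")
    attr(out, "mc_se") <- mean(se[upper.tri(se)])
  out
}

#' Empirical similarity matrix from observed triplet choices
#'
#' The behavioral analogue of [marginal_similarity()]: for each image pair
#' (i, j) and context k, the fraction of trials with reference in `{i, j}`,
#' options the other of `{i, j}` and k, in which the `{i, j}` member was
#' chosen; averaged first within each (pair, context) cell and then across
#' contexts. Pairs never co-presented with the same reference convention are
#' `NA` (flagged, never imputed).
#'
#' @param trials Trial `data.frame`.
#' @param images Image metadata (defines matrix order).
#' @return A `similarity_matrix` with `NA` for unobserved pairs and attribute
#'   `n_missing` (count of unobserved off-diagonal pairs, upper triangle).
#' @export
behavioral_similarity <- function(trials, images) {
  ids <- images$image_id
  n <- length(ids)
  r <- match(trials$reference, ids)
  a <- match(trials$option_a, ids)
  b <- match(trials$option_b, ids)
  y <- trials$choice == "A"
  # each trial scores both (ref, option) pairs in the context of the other
  dt <- data.table::data.table(
    p1 = pmin(c(r, r), c(a, b)),
    p2 = pmax(c(r, r), c(a, b)),
    ctx = c(b, a),
    y = c(y, !y))
  cell <- dt[, list(m = mean(y)), by = c("p1", "p2", "ctx")]
  pair <- cell[, list(sim = mean(m)), by = c("p1", "p2")]
  sim <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  sim[cbind(pair$p1, pair$p2)] <- pair$sim
  sim[cbind(pair$p2, pair$p1)] <- pair$sim
  diag(sim) <- 1
  miss <- sum(is.na(sim[upper.tri(sim)]))
  if (miss > 0)
    warning(miss, " image pair(s) never co-presented; entries left NA")
  structure(sim, class = c("similarity_matrix", "matrix"),
            n_missing = miss)
}

#' Write / read a similarity matrix as square CSV
#'
#' Image ids as header row and first column; missing entries as empty cells.
#'
#' @param sim A `similarity_matrix`.
#' @param path Output CSV path.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(image_id = rownames(sim), as.data.frame(unclass(sim)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$image_id
  structure(m, class = c("similarity_matrix", "matrix"))
}
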