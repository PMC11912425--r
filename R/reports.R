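#' Cluster embedding dimensions and summarize their correlations
#'
#' Treats each dimension as its value profile across all images, computes
#' pairwise distances between profiles, runs agglomerative clustering, and
#' reports the dimension correlation matrix with summary statistics.
#'
#' @param embedding Weight matrix (`n_images x n_dims`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param metric Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @return List with `hclust` (the dendrogram object), `cor_matrix`, and
#'   `cor_summary` (mean, sd, min, max over off-diagonal correlations).
#' @export
cluster_dimensions <- function(embedding, linkage = "average",
                               metric = "euclidean") {
  D <- dist(t(embedding), method = metric)
  hc <- hclust(D, method = linkage)
  cm <- cor(embedding)
  off <- cm[lower.tri(cm)]
  list(hclust = hc, cor_matrix = cm,
       cor_summary = c(mean = mean(off), sd = sd(off), min = min(off),
                       max = max(off)))
}

#' Export a 2-D map of the similarity space
#'
#' t-SNE on distances derived from the similarity matrix (or Euclidean
#' distances between embedding rows), initialized from classical MDS and run
#' with a dual-perplexity affinity (the symmetrized input affinities computed
#' at the two perplexities are averaged) for a fixed number of iterations.
#'
#' @param x A `similarity_matrix` (converted to distances as `1 - s`) or an
#'   embedding matrix (Euclidean row distances).
#' @param perplexities Two (or more) perplexities whose affinities are
#'   averaged; default `c(5, 30)`.
#' @param n_iter Gradient iterations (default 1000).
#' @param seed Integer seed (t-SNE jitter).
#' @return A `data.frame` with `image_id`, `x`, `y`.
#' @export
export_map <- function(x, perplexities = c(5, 30), n_iter = 1000, seed = 1) {
  if (inherits(x, "similarity_matrix")) {
    D <- 1 - unclass(x)
    diag(D) <- 0
    D[D < 0] <- 0
  } else {
    D <- as.matrix(dist(x))
  }
  ids <- rownames(D)
  n <- nrow(D)
  perplexities <- perplexities[perplexities < (n - 1) / 3]
  if (length(perplexities) == 0) perplexities <- max(2, floor((n - 1) / 4))
  P <- Reduce(`+`, lapply(perplexities, function(pp)
    .tsne_affinities(D, pp))) / length(perplexities)
  Y <- .tsne_run(P, D, n_iter = n_iter, seed = seed)
  data.frame(image_id = if (is.null(ids)) as.character(seq_len(n)) else ids,
             x = Y[, 1], y = Y[, 2], stringsAsFactors = FALSE)
}

# symmetrized input affinities at one perplexity (binary search on precision)
.tsne_affinities <- function(D, perplexity, tol = 1e-5) {
  n <- nrow(D)
  D2 <- D^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
                                          else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
                                 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

.tsne_run <- function(P, D, n_iter, seed, momentum0 = 0.5, momentum1 = 0.8,
                      lr = NULL, exaggeration = 12, exag_iter = 250) {
  set.seed(seed)
  n <- nrow(P)
  # learning-rate heuristic n / exaggeration: stable across problem sizes
  if (is.null(lr)) lr <- max(n / exaggeration, 2)
  exag_iter <- min(exag_iter, floor(n_iter / 4))
  # classical MDS initialization, scaled to the conventional small spread
  Y <- tryCatch(cmdscale(as.dist(D), k = 2), error = function(e) NULL)
  if (is.null(Y) || ncol(Y) < 2)
    Y <- matrix(rnorm(n * 2), n, 2)
  Y <- scale(Y, scale = FALSE)
  if (sd(Y) > 0) Y <- Y / sd(Y) * 1e-4
  Y <- Y + matrix(rnorm(n * 2, 0, 1e-6), n, 2)
  dY <- matrix(0, n, 2)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exag_iter) P * exaggeration else P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, .Machine$double.eps)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= exag_iter) momentum0 else momentum1
    dY <- mom * dY - lr * grad
    Y <- Y + dY
    Y <- scale(Y, scale = FALSE)
  }
  Y
}
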