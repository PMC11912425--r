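#' Generate a ground-truth sparse nonnegative embedding
#'
#' Builds a synthetic "true" embedding with class structure mimicking a
#' materials stimulus set: each class has a sparse nonnegative prototype
#' (Bernoulli support mask times Gamma-distributed magnitudes), and each
#' exemplar is the prototype plus nonnegative noise restricted to the
#' prototype's support, rescaled back to the prototype's norm so that scale is
#' stable across exemplars. Exemplars of a class therefore share a support and
#' are more correlated with each other than with other classes.
#'
#' @param n_classes Number of material classes.
#' @param exemplars_per_class Exemplars (images) per class, default 3.
#' @param k_dims Number of true dimensions.
#' @param sparsity Probability that a dimension is expressed in a class
#'   prototype (support mask density).
#' @param exemplar_noise Scale of the half-normal within-class noise, as a
#'   fraction of the Gamma magnitude scale (default 0.15).
#' @param gamma_shape,gamma_scale Magnitude distribution (default Gamma(2, 0.5):
#'   positive and right-skewed, like fitted sparse-embedding weights).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return An object of class `ground_truth`: a list with `embedding`
#'   (matrix, image ids as rownames), `images` (metadata data.frame),
#'   `params`, `seed`.
#' @export
make_ground_truth <- function(n_classes, exemplars_per_class = 3, k_dims,
                              sparsity, exemplar_noise = 0.15,
                              gamma_shape = 2, gamma_scale = 0.5,
                              seed = 1) {
  stopifnot(n_classes >= 1, exemplars_per_class >= 1, k_dims >= 1,
            sparsity >= 0, sparsity <= 1)
  set.seed(seed)
  n <- n_classes * exemplars_per_class
  classes <- sprintf("class%03d", seq_len(n_classes))
  mask <- matrix(rbinom(n_classes * k_dims, 1, sparsity),
                 n_classes, k_dims)
  proto <- mask * matrix(rgamma(n_classes * k_dims, shape = gamma_shape,
                                scale = gamma_scale), n_classes, k_dims)
  W <- matrix(0, n, k_dims)
  image_id <- character(n)
  class_label <- character(n)
  exemplar_index <- integer(n)
  row <- 0L
  for (c in seq_len(n_classes)) {
    pn <- sqrt(sum(proto[c, ]^2))
    for (e in seq_len(exemplars_per_class)) {
      row <- row + 1L
      noise <- abs(rnorm(k_dims, 0, exemplar_noise * gamma_scale)) * mask[c, ]
      v <- proto[c, ] + noise
      vn <- sqrt(sum(v^2))
      if (vn > 0 && pn > 0) v <- v * (pn / vn)
      W[row, ] <- v
      image_id[row] <- sprintf("%s_ex%d", classes[c], e)
      class_label[row] <- classes[c]
      exemplar_index[row] <- e
    }
  }
  rownames(W) <- image_id
  colnames(W) <- sprintf("dim%d", seq_len(k_dims))
  structure(list(
    embedding = W,
    images = data.frame(image_id = image_id, class_label = class_label,
                        exemplar_index = exemplar_index,
                        stringsAsFactors = FALSE),
    params = list(n_classes = n_classes,
                  exemplars_per_class = exemplars_per_class,
                  k_dims = k_dims, sparsity = sparsity,
                  exemplar_noise = exemplar_noise,
                  gamma_shape = gamma_shape, gamma_scale = gamma_scale),
    seed = seed), class = "ground_truth")
}

#' Worker profiles for simulated triplet responders
#'
#' @param type One of `"clean"`, `"fast_responder"`, `"position_biased"`.
#' @param lapse_rate Probability in `[0, 0.5]` that the model-based choice is
#'   flipped (0.5 makes responses a fair coin).
#' @param rt_meanlog,rt_sdlog Log-normal response-time parameters
#'   (milliseconds). Defaults give slow, plausible RTs for clean workers and
#'   sub-600 ms RTs for fast responders.
#' @param position_bias Probability that a position-biased worker answers at
#'   their preferred screen position regardless of the stimuli.
#' @return A `worker_profile` list.
#' @export
worker_profile <- function(type = c("clean", "fast_responder",
                                    "position_biased"),
                           lapse_rate = 0.05,
                           rt_meanlog = NULL, rt_sdlog = 0.25,
                           position_bias = 0.9) {
  type <- match.arg(type)
  stopifnot(lapse_rate >= 0, lapse_rate <= 0.5)
  if (is.null(rt_meanlog))
    rt_meanlog <- switch(type, fast_responder = log(400), log(1500))
  structure(list(type = type, lapse_rate = lapse_rate,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 position_bias = position_bias),
            class = "worker_profile")
}

#' Simulate triplet 2-AFC trials from a ground truth
#'
#' Draws triplet contexts (uniformly at random, or the fully enumerated
#' design), generates choices from the softmax of reference-option dot
#' products under the ground-truth embedding, applies per-worker lapses and
#' position bias, and attaches response times and screen positions per worker
#' profile. Also reports the generator's own Bayes accuracy: the mean of
#' `max(p, 1 - p)` over the sampled triplets under the noise-free model, the
#' ceiling any observer of pooled choices could reach.
#'
#' @param truth A `ground_truth` object.
#' @param n_trials Number of trials (ignored when `design = "full"`).
#' @param design `"random"` (uniform triplet contexts) or `"full"` (every
#'   unordered 3-image context once per reference assignment, times
#'   `n_repeats`).
#' @param n_repeats Repeats of the full design (default 1).
#' @param workers List of `worker_profile` objects with mixing fractions in
#'   `worker_fractions`; trials are dealt to workers in contiguous blocks.
#' @param worker_fractions Numeric vector summing to 1, one entry per profile.
#' @param n_workers Number of simulated workers (default: one per 200 trials,
#'   at least 2).
#' @param seed Integer seed.
#' @return A trial `data.frame` in the [read_trials()] schema with attributes
#'   `bayes_accuracy` (percent) and `worker_types` (named character vector).
#' @export
simulate_trials <- function(truth, n_trials = NULL,
                            design = c("random", "full"), n_repeats = 1,
                            workers = list(worker_profile("clean")),
                            worker_fractions = 1,
                            n_workers = NULL, seed = 1) {
  design <- match.arg(design)
  W <- truth$embedding
  n <- nrow(W)
  if (n < 3) stop("need at least 3 images to form triplets")
  stopifnot(abs(sum(worker_fractions) - 1) < 1e-8,
            length(worker_fractions) == length(workers))
  set.seed(seed)

  if (design == "full") {
    ctx <- t(combn(n, 3))
    # each unordered context once per reference assignment
    trip <- rbind(ctx[, c(1, 2, 3)], ctx[, c(2, 1, 3)], ctx[, c(3, 1, 2)])
    trip <- trip[rep(seq_len(nrow(trip)), n_repeats), , drop = FALSE]
  } else {
    stopifnot(!is.null(n_trials), n_trials >= 1)
    trip <- .draw_triplets(n_trials, n)
  }
  nt <- nrow(trip)
  # randomize which option is "A"
  swap <- runif(nt) < 0.5
  trip[swap, 2:3] <- trip[swap, 3:2]

  r <- trip[, 1]; a <- trip[, 2]; b <- trip[, 3]
  sa <- rowSums(W[r, , drop = FALSE] * W[a, , drop = FALSE])
  sb <- rowSums(W[r, , drop = FALSE] * W[b, , drop = FALSE])
  p_a <- .sigmoid(sa - sb)
  bayes <- 100 * mean(pmax(p_a, 1 - p_a))

  if (is.null(n_workers)) n_workers <- max(2L, ceiling(nt / 200))
  prof_of_worker <- sample(rep(seq_along(workers),
                               round2count(worker_fractions, n_workers)))
  worker_of_trial <- sort(rep_len(seq_len(n_workers), nt))
  wid <- sprintf("w%04d", worker_of_trial)

  lapse <- vapply(workers, `[[`, numeric(1), "lapse_rate")[prof_of_worker]
  mlog <- vapply(workers, `[[`, numeric(1), "rt_meanlog")[prof_of_worker]
  slog <- vapply(workers, `[[`, numeric(1), "rt_sdlog")[prof_of_worker]
  type <- vapply(workers, `[[`, character(1), "type")[prof_of_worker]
  pbias <- vapply(workers, `[[`, numeric(1), "position_bias")[prof_of_worker]
  pref_pos <- sample(c("left", "right"), n_workers, replace = TRUE)

  # a lapse flips the model-based choice: lapse 0.5 is a fair coin
  p_eff <- (1 - lapse[worker_of_trial]) * p_a +
    lapse[worker_of_trial] * (1 - p_a)
  choose_a <- runif(nt) < p_eff
  pos_of_a <- sample(c("left", "right"), nt, replace = TRUE)
  # position-biased workers answer at their preferred position with prob pbias
  biased <- type[worker_of_trial] == "position_biased" &
    runif(nt) < pbias[worker_of_trial]
  pref <- pref_pos[worker_of_trial]
  choose_a[biased] <- (pos_of_a == pref)[biased]
  rt <- rlnorm(nt, mlog[worker_of_trial], slog[worker_of_trial])

  ids <- rownames(W)
  out <- data.frame(
    worker_id = wid,
    reference = ids[r],
    option_a = ids[a],
    option_b = ids[b],
    choice = ifelse(choose_a, "A", "B"),
    rt_ms = round(rt, 1),
    position = ifelse(choose_a, pos_of_a,
                      ifelse(pos_of_a == "left", "right", "left")),
    stringsAsFactors = FALSE)
  attr(out, "bayes_accuracy") <- bayes
  attr(out, "worker_types") <- setNames(type, sprintf("w%04d",
                                                      seq_len(n_workers)))
  out
}

# uniform ordered triplets with pairwise-distinct entries, by rejection
.draw_triplets <- function(nt, n) {
  draw <- function(m) matrix(sample.int(n, 3 * m, replace = TRUE), m, 3)
  trip <- draw(nt)
  repeat {
    bad <- which(trip[, 1] == trip[, 2] | trip[, 1] == trip[, 3] |
                   trip[, 2] == trip[, 3])
    if (!length(bad)) break
    trip[bad, ] <- draw(length(bad))
  }
  trip
}

# apportion n items to fractions, largest-remainder
round2count <- function(frac, n) {
  raw <- frac * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a repeated-triplet subset for ceiling estimation
#'
#' Samples `n_triplets` distinct triplets and presents each `m` times (to
#' distinct simulated workers), tagging rows with a `repeat_block` id, so the
#' intersubject consistency ceiling can be estimated exactly as in a repeated
#' design.
#'
#' @param truth A `ground_truth` object.
#' @param n_triplets Number of unique triplets.
#' @param m Responses per triplet (at least 2).
#' @param lapse_rate Lapse applied to every simulated response.
#' @param seed Integer seed.
#' @return A trial `data.frame` with a `repeat_block` column and attribute
#'   `true_probs` (the noise-free model probability of option A per block).
#' @export
make_repeated_set <- function(truth, n_triplets, m = 60, lapse_rate = 0,
                              seed = 1) {
  stopifnot(m >= 2)
  W <- truth$embedding
  n <- nrow(W)
  set.seed(seed)
  trip <- .draw_triplets(n_triplets, n)
  r <- trip[, 1]; a <- trip[, 2]; b <- trip[, 3]
  sa <- rowSums(W[r, , drop = FALSE] * W[a, , drop = FALSE])
  sb <- rowSums(W[r, , drop = FALSE] * W[b, , drop = FALSE])
  p_a <- .sigmoid(sa - sb)
  p_eff <- (1 - lapse_rate) * p_a + lapse_rate * (1 - p_a)
  idx <- rep(seq_len(n_triplets), each = m)
  choose_a <- runif(n_triplets * m) < p_eff[idx]
  ids <- rownames(W)
  out <- data.frame(
    worker_id = sprintf("rw%05d", seq_len(n_triplets * m)),
    reference = ids[r][idx],
    option_a = ids[a][idx],
    option_b = ids[b][idx],
    choice = ifelse(choose_a, "A", "B"),
    rt_ms = 1500,
    repeat_block = sprintf("block%05d", idx),
    stringsAsFactors = FALSE)
  attr(out, "true_probs") <- p_a
  out
}

#' Generate class-level semantic vectors correlated with the ground truth
#'
#' Produces one vector per class as a linear mixture of the class prototypes
#' (mean exemplar embedding per class) plus Gaussian noise: `coupling = 0`
#' gives vectors independent of the truth, `coupling = 1` a noiseless linear
#' projection. Stands in for word-embedding vectors of the class names.
#'
#' @param truth A `ground_truth` object.
#' @param coupling Mixing weight in `[0, 1]`.
#' @param dim Vector dimensionality (default 300).
#' @param seed Integer seed.
#' @return A `n_classes x dim` matrix with class labels as rownames.
#' @export
make_semantic_vectors <- function(truth, coupling, dim = 300, seed = 1) {
  stopifnot(coupling >= 0, coupling <= 1)
  set.seed(seed)
  cls <- unique(truth$images$class_label)
  proto <- t(vapply(cls, function(cl) {
    colMeans(truth$embedding[truth$images$class_label == cl, , drop = FALSE])
  }, numeric(ncol(truth$embedding))))
  mix <- matrix(rnorm(ncol(proto) * dim), ncol(proto), dim)
  signal <- scale(proto %*% mix)
  signal[is.nan(signal)] <- 0
  noise <- matrix(rnorm(length(cls) * dim), length(cls), dim)
  out <- coupling * signal + (1 - coupling) * noise
  rownames(out) <- cls
  out
}

#' Generate image feature vectors correlated with the ground truth
#'
#' Emulates deep-network image features: a random nonnegative mixing of the
#' true dimensions plus Gaussian noise. The mixing matrix is stored as an
#' attribute so recovery can be checked against an oracle.
#'
#' @param truth A `ground_truth` object.
#' @param n_features Number of features.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return An `n_images x n_features` matrix (image ids as rownames) with
#'   attribute `mixing`.
#' @export
make_feature_vectors <- function(truth, n_features, noise_sd = 0, seed = 1) {
  set.seed(seed)
  W <- truth$embedding
  mix <- matrix(abs(rnorm(ncol(W) * n_features)), ncol(W), n_features)
  out <- W %*% mix +
    matrix(rnorm(nrow(W) * n_features, 0, noise_sd), nrow(W), n_features)
  rownames(out) <- rownames(W)
  colnames(out) <- sprintf("f%d", seq_len(n_features))
  attr(out, "mixing") <- mix
  out
}
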