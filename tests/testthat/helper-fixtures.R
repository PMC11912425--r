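# shared fixture builders; everything is generated in code, nothing on disk

tiny_truth <- function(n_classes = 8, k_dims = 5, sparsity = 0.5, seed = 3) {
  make_ground_truth(n_classes = n_classes, k_dims = k_dims,
                    sparsity = sparsity, seed = seed)
}

# a hand-built image table and trial table for reader/QC tests
toy_images <- function(n = 6) {
  data.frame(image_id = sprintf("img%02d", seq_len(n)),
             class_label = rep(sprintf("cls%d", seq_len(ceiling(n / 3))),
                               each = 3)[seq_len(n)],
             exemplar_index = rep(1:3, length.out = n),
             stringsAsFactors = FALSE)
}

toy_trials <- function(worker = "w1", n = 4, rt = 1500, images = toy_images(),
                       position = NULL) {
  ids <- images$image_id
  base <- data.frame(worker_id = worker,
                     reference = ids[1 + (seq_len(n) - 1) %% 3],
                     option_a = ids[4], option_b = ids[5],
                     choice = rep(c("A", "B"), length.out = n),
                     rt_ms = rep_len(rt, n),
                     stringsAsFactors = FALSE)
  if (!is.null(position)) base$position <- rep_len(position, n)
  base
}

write_trials_csv <- function(trials, path = tempfile(fileext = ".csv")) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  path
}

# scalar-loop choice probability oracle, independent of the package's path
oracle_choice_prob <- function(W, r, a, b) {
  sa <- sum(W[r, ] * W[a, ])
  sb <- sum(W[r, ] * W[b, ])
  exp(sa) / (exp(sa) + exp(sb))
}

# triple-loop marginal similarity oracle
oracle_marginal_similarity <- function(W) {
  n <- nrow(W)
  S <- W %*% t(W)
  sig <- function(z) 1 / (1 + exp(-z))
  out <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      acc <- 0
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        acc <- acc + (sig(S[i, j] - S[i, k]) + sig(S[j, i] - S[j, k])) / 2
      }
      out[i, j] <- out[j, i] <- acc / (n - 2)
    }
  }
  out
}

# random evaluation triplets over a set of image ids
.draw_eval_triplets <- function(ids, n, seed = 1) {
  set.seed(seed)
  m <- t(replicate(n, sample(ids, 3)))
  data.frame(reference = m[, 1], option_a = m[, 2], option_b = m[, 3],
             stringsAsFactors = FALSE)
}

# exact E[max(c, m - c)] / m under Binomial(m, p), for the ceiling estimator
oracle_expected_modal_fraction <- function(p, m) {
  vapply(p, function(pp) {
    c0 <- 0:m
    sum(pmax(c0, m - c0) / m * stats::dbinom(c0, m, pp))
  }, numeric(1))
}
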