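test_that("consistency ceiling is the mean modal-response fraction", {
  # one triplet, counts (45, 15) of 60 -> 75%
  tr <- data.frame(worker_id = sprintf("w%d", 1:60),
                   reference = "r", option_a = "a", option_b = "b",
                   choice = rep(c("A", "B"), c(45, 15)), rt_ms = 1000,
                   repeat_block = "b1", stringsAsFactors = FALSE)
  expect_equal(as.numeric(consistency_ceiling(tr)), 75)
  # unanimity -> 100
  tr$choice <- "A"
  expect_equal(as.numeric(consistency_ceiling(tr)), 100)
  # modal counts follow the option image, not the A/B slot
  swapped <- tr
  swapped$option_a <- "b"; swapped$option_b <- "a"; swapped$choice <- "B"
  expect_equal(as.numeric(consistency_ceiling(rbind(tr, swapped))), 100)
})

test_that("simulated repeats recover the expected ceiling", {
  truth <- tiny_truth(seed = 40)
  reps <- make_repeated_set(truth, n_triplets = 400, m = 60, seed = 41)
  got <- as.numeric(consistency_ceiling(reps))
  p <- attr(reps, "true_probs")
  # exact finite-sample expectation of the estimator (independent oracle)
  expected <- 100 * mean(oracle_expected_modal_fraction(p, 60))
  se <- 100 * sd(oracle_expected_modal_fraction(p, 60)) / sqrt(length(p))
  expect_lt(abs(got - expected), 4 * se)
  # and within ~1.5 points of the asymptotic mean max(p, 1 - p)
  expect_lt(abs(got - 100 * mean(pmax(p, 1 - p))), 1.5)
})

test_that("chance correction matches its closed form and is shift-invariant", {
  # on the printed (rounded) inputs the ratio is 21.86/23.84 = 91.69...%,
  # one hundredth under the headline figure computed from unrounded inputs
  expect_equal(round(chance_corrected(71.86, 73.84), 1), 91.7)
  expect_equal(chance_corrected(71.86, 73.84), 100 * 21.86 / 23.84)
  expect_equal(chance_corrected(73.84, 73.84), 100)
  expect_equal(chance_corrected(50, 73.84), 0)
  expect_equal(chance_corrected(60 + 5, 70 + 5, 50 + 5),
               chance_corrected(60, 70, 50))
  expect_error(chance_corrected(60, 50, 50), "undefined")
  expect_error(chance_corrected(60, 45, 50), "undefined")
})

test_that("matrix comparison is exact on identity and label-aligned inputs", {
  set.seed(50)
  W <- matrix(abs(rnorm(60)), 15, 4,
              dimnames = list(sprintf("i%02d", 1:15), NULL))
  A <- marginal_similarity(W)
  out <- compare_matrices(A, A, n_perm = 200, n_boot = 100, seed = 1)
  expect_equal(out$r, 1)
  expect_lt(out$p, 0.05)
  # a row/column permutation with matching labels must still align
  p <- sample(15)
  B <- A[p, p]
  out2 <- compare_matrices(A, B, n_perm = 200, n_boot = 100, seed = 1)
  expect_equal(out2$r, 1)
})

test_that("the permutation null is well calibrated for independent matrices", {
  set.seed(51)
  n <- 20
  pvals <- replicate(40, {
    A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 1
    B <- matrix(runif(n * n), n, n); B <- (B + t(B)) / 2; diag(B) <- 1
    rownames(A) <- colnames(A) <- rownames(B) <- colnames(B) <-
      sprintf("i%d", 1:n)
    compare_matrices(A, B, n_perm = 99, n_boot = 10,
                     seed = sample.int(1e6, 1))$p
  })
  # under the null, p-values should not pile up near zero
  expect_gt(mean(pvals > 0.1), 0.6)
  expect_gt(min(pvals), 0.005)
})

test_that("split-half reliability applies the Spearman-Brown step-up", {
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(0.9417), 2 * 0.9417 / 1.9417)
  expect_equal(round(spearman_brown(0.9417), 2), 0.97)

  truth <- tiny_truth(n_classes = 5, k_dims = 4, seed = 60)
  tr <- simulate_trials(truth, design = "full", n_repeats = 4,
                        workers = list(worker_profile("clean",
                                                      lapse_rate = 0.1)),
                        seed = 61)
  out <- split_half_reliability(tr, truth$images, n_splits = 3, seed = 62)
  expect_equal(out$r_corrected, spearman_brown(out$r_half))
  expect_gt(out$r_corrected, 0.5)
  expect_length(out$r_half_all, 3)
})

test_that("explainable variance follows the reliability-normalized formula", {
  expect_equal(explainable_variance(1, 1), 100)
  expect_equal(explainable_variance(0, 0.9), 0)
  expect_equal(round(explainable_variance(0.90, 0.97), 1), 83.5)
})

test_that("within-class similarity exceeds between on block structure", {
  images <- data.frame(image_id = sprintf("i%d", 1:6),
                       class_label = rep(c("c1", "c2"), each = 3),
                       exemplar_index = rep(1:3, 2),
                       stringsAsFactors = FALSE)
  sim <- matrix(0.4, 6, 6, dimnames = list(images$image_id,
                                           images$image_id))
  sim[1:3, 1:3] <- 0.9; sim[4:6, 4:6] <- 0.9; diag(sim) <- 1
  # slight jitter so the paired t is defined
  sim[1, 2] <- sim[2, 1] <- 0.89
  out <- within_between_class(sim, images)
  expect_equal(out$within_mean, mean(c(0.89, 0.9, 0.9, 0.9, 0.9, 0.9)),
               tolerance = 1e-12)
  expect_equal(out$between_mean, 0.4)
  expect_gt(out$t, 0)
  expect_equal(out$df, 1)

  flat <- matrix(0.5, 6, 6, dimnames = dimnames(sim)); diag(flat) <- 1
  expect_warning(res <- within_between_class(flat, images), "degenerate")
  expect_true(is.nan(res$t))
})

test_that("class structure in the generator yields within > between", {
  truth <- tiny_truth(n_classes = 10, k_dims = 5, seed = 70)
  sim <- marginal_similarity(truth$embedding)
  out <- within_between_class(sim, truth$images)
  expect_gt(out$within_mean, out$between_mean)
  expect_gt(out$t, 2)
})

test_that("decoding is perfect for orthogonal classes and chance when shuffled", {
  # identical exemplars within class, orthogonal one-hot classes
  nc <- 6
  W <- kronecker(diag(nc), matrix(1, 3, 1))
  rownames(W) <- sprintf("i%02d", seq_len(3 * nc))
  images <- data.frame(image_id = rownames(W),
                       class_label = rep(sprintf("c%d", 1:nc), each = 3),
                       exemplar_index = rep(1:3, nc),
                       stringsAsFactors = FALSE)
  out <- decode_classes(W, images)
  expect_equal(out$top1, 100)
  expect_equal(out$pairwise_acc, 100)
  expect_equal(out$median_rank, 1)

  # shuffled labels drop top-1 to ~chance
  set.seed(71)
  shuf <- images
  shuf$class_label <- sample(shuf$class_label)
  out2 <- decode_classes(W, shuf)
  expect_lt(out2$top1, 50)
})

test_that("pairwise decoding equals exhaustive per-pair evaluation", {
  set.seed(72)
  W <- matrix(abs(rnorm(12 * 4)), 12, 4,
              dimnames = list(sprintf("i%02d", 1:12), NULL))
  images <- data.frame(image_id = rownames(W),
                       class_label = rep(sprintf("c%d", 1:4), each = 3),
                       exemplar_index = rep(1:3, 4),
                       stringsAsFactors = FALSE)
  out <- decode_classes(W, images)
  # independent oracle: loop over the 6 class pairs and 3 folds by hand
  accs <- c()
  for (ci in 1:3) for (cj in (ci + 1):4) {
    cl <- images$class_label
    sel <- cl %in% sprintf("c%d", c(ci, cj))
    for (f in 1:3) {
      trn <- sel & images$exemplar_index != f
      tst <- sel & images$exemplar_index == f
      fit <- e1071::svm(W[trn, ], factor(cl[trn]), kernel = "linear",
                        cost = 1, scale = FALSE)
      accs <- c(accs, mean(as.character(predict(fit, W[tst, , drop = FALSE]))
                           == cl[tst]))
    }
  }
  expect_equal(out$pairwise_acc, 100 * mean(accs), tolerance = 1e-9)
})

test_that("semantic comparison is exact for self-derived matrices", {
  truth <- tiny_truth(n_classes = 12, k_dims = 6, seed = 80)
  sim <- marginal_similarity(truth$embedding)
  # semantic vectors equal to the class-aggregated behavioral matrix rows
  cls <- unique(truth$images$class_label)
  beh <- matrix(NA, length(cls), length(cls),
                dimnames = list(cls, cls))
  cl <- truth$images$class_label
  for (i in seq_along(cls)) for (j in seq_along(cls))
    beh[i, j] <- mean(sim[cl == cls[i], cl == cls[j]])
  # identical matrices -> R^2 exactly 1
  out_ident <- semantic_comparison(sim, truth$images, semantic_matrix = beh)
  expect_equal(out_ident$r_squared, 1)
  # class-aggregated rows as vectors stay strongly related
  out_rows <- semantic_comparison(sim, truth$images, beh)
  expect_gt(out_rows$r_squared, 0.5)
  # independent random vectors: small R^2
  set.seed(81)
  rand <- matrix(rnorm(length(cls) * 50), length(cls), 50,
                 dimnames = list(cls, NULL))
  expect_lt(semantic_comparison(sim, truth$images, rand)$r_squared, 0.3)
})

test_that("choice-probability agreement is near-perfect for the true model", {
  truth <- tiny_truth(seed = 85)
  reps <- make_repeated_set(truth, n_triplets = 250, m = 60, seed = 86)
  out <- choice_prob_agreement(truth$embedding, reps)
  expect_gt(out$r, 0.9)
  expect_gt(out$accuracy_pct, 90)
  expect_equal(out$n_triplets, 250)
})

test_that("the pruning curve finds the per-image sparsity of the truth", {
  # construct an embedding with exactly 3 dominant dims per image
  set.seed(90)
  n <- 30; k <- 10
  W <- matrix(0, n, k, dimnames = list(sprintf("i%02d", 1:n), NULL))
  for (i in seq_len(n))
    W[i, sample(k, 3)] <- 2 + abs(rnorm(3))
  truth_like <- list(embedding = W)
  trips <- .draw_eval_triplets(rownames(W), 2000, seed = 91)
  out <- dimension_pruning_curve(W, trips)
  expect_lte(out$dims_95, 4)
  expect_equal(out$curve$r_squared[1], 1)
  # monotone non-increasing as dimensions are removed
  expect_true(all(diff(rev(out$curve$r_squared)) >= -1e-8))

  # a 1-sparse embedding is flat at 100%
  W1 <- matrix(0, 10, 4, dimnames = list(sprintf("j%d", 1:10), NULL))
  W1[cbind(1:10, rep(1:4, length.out = 10))] <- 1
  trips1 <- .draw_eval_triplets(rownames(W1), 200, seed = 92)
  out1 <- dimension_pruning_curve(W1, trips1)
  expect_true(all(out1$curve$r_squared == 1))
  expect_equal(out1$dims_95, 1)
})
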