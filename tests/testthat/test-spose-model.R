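test_that("choice probability follows the softmax over dot products", {
  W <- matrix(0, 3, 2, dimnames = list(c("i", "j", "k"), NULL))
  expect_equal(choice_probability(W, "i", "j", "k"), 0.5)

  # dot products ln 3 and 0 give p = 0.75
  W2 <- rbind(i = c(1, 0), j = c(log(3), 0), k = c(0, 1))
  expect_equal(choice_probability(W2, "i", "j", "k"), 0.75)

  expect_error(choice_probability(W, "i", "j", "zz"), "zz")
  expect_error(choice_probability(W, "i", "i", "j"), "distinct")
})

test_that("vectorized choice probabilities match a scalar-loop oracle", {
  set.seed(44)
  W <- matrix(abs(rnorm(15)), 5, 3,
              dimnames = list(letters[1:5], NULL))
  trips <- t(combn(5, 3))
  for (row in seq_len(nrow(trips))) {
    ids <- letters[trips[row, ]]
    got <- choice_probability(W, ids[1], ids[2], ids[3])
    expect_equal(got, oracle_choice_prob(W, ids[1], ids[2], ids[3]),
                 tolerance = 1e-12)
    # complementarity of the two options
    expect_equal(got + choice_probability(W, ids[1], ids[3], ids[2]), 1,
                 tolerance = 1e-12)
  }
})

test_that("choice probability is invariant to appending all-zero dimensions", {
  set.seed(45)
  W <- matrix(abs(rnorm(12)), 4, 3, dimnames = list(letters[1:4], NULL))
  Wz <- cbind(W, 0, 0)
  expect_equal(choice_probability(W, "a", "b", "c"),
               choice_probability(Wz, "a", "b", "c"), tolerance = 1e-15)
})

test_that("fitting is deterministic and keeps weights nonnegative", {
  truth <- tiny_truth(seed = 30)
  tr <- simulate_trials(truth, n_trials = 5000,
                        workers = list(worker_profile("clean",
                                                      lapse_rate = 0.05)),
                        seed = 6)
  cfg <- fit_config(n_init_dims = 10, lambda = 0.3, max_epochs = 40,
                    patience = 5, seed = 77)
  f1 <- fit_embedding(tr, truth$images, cfg)
  f2 <- fit_embedding(tr, truth$images, cfg)
  expect_identical(f1$embedding, f2$embedding)
  expect_true(all(f1$embedding >= 0))
  # training loss decreases from its starting point
  expect_lt(min(f1$train_loss), f1$train_loss[1])
  # informative data: held-out accuracy is clearly above chance
  expect_gt(f1$test_accuracy, 0.55)
})

test_that("an overwhelming penalty drives all weights to zero", {
  truth <- tiny_truth(seed = 31)
  tr <- simulate_trials(truth, n_trials = 3000, seed = 7)
  cfg <- fit_config(n_init_dims = 8, lambda = 1e4, max_epochs = 30,
                    patience = 30, seed = 1)
  f <- fit_embedding(tr, truth$images, cfg)
  expect_lt(max(f$embedding), 1e-3)
  # with a flat model every prediction is 0.5: accuracy ~ chance
  expect_lt(abs(f$test_accuracy - 0.5), 0.1)
})

test_that("pruning drops only near-zero dimensions and reindexes", {
  W <- cbind(dim1 = c(0.5, 1, 0.2), dim2 = c(0, 0, 0),
             dim3 = c(0.4, 0.3, 0.9))
  rownames(W) <- letters[1:3]
  pr <- prune_dimensions(W, tol = 0.1)
  expect_equal(pr$n_pruned, 1)
  expect_equal(colnames(pr$embedding), c("dim1", "dim2"))
  expect_equal(unname(pr$embedding[, 2]), c(0.4, 0.3, 0.9))
  # infinitesimal tolerance keeps strictly positive columns
  pr2 <- prune_dimensions(W[, c(1, 3)], tol = 1e-12)
  expect_equal(pr2$n_pruned, 0)
})

test_that("dimension ordering sorts by mean weight with stable ties", {
  W <- cbind(a = rep(0.4, 3), b = rep(0.9, 3))
  out <- order_dimensions(W)
  expect_equal(unname(out[1, ]), c(0.9, 0.4))
  # equal means keep the original order
  We <- cbind(x = c(0.1, 0.5), y = c(0.5, 0.1))
  oute <- order_dimensions(We)
  expect_equal(unname(oute[, 1]), c(0.1, 0.5))
  # conservation: the multiset of columns is unchanged
  set.seed(3)
  Wr <- matrix(abs(rnorm(20)), 5, 4)
  outr <- order_dimensions(Wr)
  expect_equal(sort(as.vector(outr)), sort(as.vector(Wr)))
  expect_setequal(apply(outr, 2, paste, collapse = ","),
                  apply(Wr, 2, paste, collapse = ","))
})

test_that("lambda selection obeys the grid and the sparser tie-break", {
  truth <- tiny_truth(n_classes = 5, k_dims = 3, seed = 33)
  tr <- simulate_trials(truth, n_trials = 4000,
                        workers = list(worker_profile("clean",
                                                      lapse_rate = 0.05)),
                        seed = 9)
  cfg1 <- fit_config(n_init_dims = 6, lambda_grid = 0.25, n_cv_folds = 2,
                     max_epochs = 25, patience = 5, seed = 2)
  expect_equal(select_lambda(tr, truth$images, cfg1)$lambda, 0.25)

  # informative data: an absurd penalty loses to no penalty
  cfg2 <- fit_config(n_init_dims = 6, lambda_grid = c(0, 1e4),
                     n_cv_folds = 2, max_epochs = 25, patience = 5, seed = 2)
  sel <- select_lambda(tr, truth$images, cfg2)
  expect_equal(sel$lambda, 0)
  expect_equal(nrow(sel$cv_table), 2)
})

test_that("parameter recovery finds the true dimensions at small scale", {
  truth <- make_ground_truth(n_classes = 15, k_dims = 4, sparsity = 0.5,
                             seed = 51)
  tr <- simulate_trials(truth, n_trials = 60000,
                        workers = list(worker_profile("clean",
                                                      lapse_rate = 0.05)),
                        seed = 52)
  cfg <- fit_config(n_init_dims = 12, lambda = 0.2, max_epochs = 120,
                    patience = 10, seed = 53)
  fit <- fit_and_prune(tr, truth$images, cfg, prune_tol = 0.1)
  expect_lte(abs(ncol(fit$embedding) - 4), 2)
  rp <- reproducibility(truth$embedding, list(fit$embedding))
  expect_gte(mean(rp$reproducibility), 0.9)
  # held-out accuracy approaches the generator's Bayes accuracy
  expect_gt(100 * fit$test_accuracy,
            attr(tr, "bayes_accuracy") - 7)
})

test_that("embedding round-trips through the TSV writer", {
  truth <- tiny_truth(seed = 60)
  path <- tempfile(fileext = ".tsv")
  write_embedding(truth$embedding, path)
  back <- read_embedding(path)
  expect_equal(back, truth$embedding, tolerance = 1e-12)
})
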