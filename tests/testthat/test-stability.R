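test_that("reproducibility is 1 for identical or column-permuted refits", {
  truth <- tiny_truth(seed = 100)
  W <- truth$embedding
  out <- reproducibility(W, list(W, W))
  expect_true(all(abs(out$reproducibility - 1) < 1e-6))
  # permutation invariance of the best-match step
  perm <- W[, c(3, 1, 5, 2, 4)]
  out2 <- reproducibility(W, list(perm))
  expect_true(all(abs(out2$reproducibility - 1) < 1e-6))
})

test_that("matching is greedy per reference dimension, not one-to-one", {
  set.seed(101)
  base <- abs(rnorm(12))
  # two near-duplicate reference dimensions both match the same run column
  W <- cbind(d1 = base, d2 = base + abs(rnorm(12, 0, 1e-3)),
             d3 = abs(rnorm(12)))
  rownames(W) <- sprintf("i%d", 1:12)
  run <- cbind(W[, 1], W[, 3], unrelated = abs(rnorm(12)))
  out <- reproducibility(W, list(run))
  expect_gt(out$run1[1], 0.99)
  expect_gt(out$run1[2], 0.99)  # both map onto run column 1
  # Hungarian assignment forces distinct matches, degrading one of them
  outh <- reproducibility(W, list(run), method = "hungarian")
  expect_lt(min(outh$run1[1:2]), min(out$run1[1:2]))
})

test_that("Fisher-z averaging clamps perfect correlations", {
  W <- tiny_truth(seed = 102)$embedding
  out <- reproducibility(W, list(W))
  expect_true(all(is.finite(out$reproducibility)))
  expect_true(all(out$reproducibility <= 1))
})

test_that("zero-variance reference dimensions are excluded with a warning", {
  W <- tiny_truth(seed = 103)$embedding
  Wz <- cbind(W, 0)
  expect_warning(out <- reproducibility(Wz, list(W)), "zero-variance")
  expect_equal(nrow(out), ncol(W))
})

test_that("independent refits on synthetic data reproduce the dimensions", {
  truth <- make_ground_truth(n_classes = 15, k_dims = 4, sparsity = 0.5,
                             seed = 110)
  tr <- simulate_trials(truth, n_trials = 60000,
                        workers = list(worker_profile("clean",
                                                      lapse_rate = 0.05)),
                        seed = 111)
  fits <- lapply(1:3, function(s) {
    cfg <- fit_config(n_init_dims = 12, lambda = 0.2, max_epochs = 120,
                      patience = 10, seed = 200 + s)
    fit_and_prune(tr, truth$images, cfg)$embedding
  })
  out <- reproducibility(fits[[1]], fits[-1])
  expect_gte(mean(out$reproducibility), 0.9)
})

test_that("subset stability removes classes, trials and reports the fraction", {
  truth <- make_ground_truth(n_classes = 10, k_dims = 4, sparsity = 0.5,
                             seed = 120)
  tr <- simulate_trials(truth, design = "full",
                        workers = list(worker_profile("clean",
                                                      lapse_rate = 0.05)),
                        seed = 121)
  cfg <- fit_config(n_init_dims = 8, lambda = 0.2, max_epochs = 60,
                    patience = 8, seed = 122)
  ref <- fit_and_prune(tr, truth$images, cfg)$embedding
  out <- subset_stability(tr, truth$images, ref, cfg,
                          removal = 0.2, n_runs = 2, seed = 123)
  # 2 of 10 classes -> 6 of 30 images; fully sampled design: combinatorial
  expect_equal(length(out$removed_classes), 2)
  expect_equal(out$trial_removal_fraction, design_removal_fraction(30, 6))
  expect_true(all(out$table$reproducibility >= -1 &
                    out$table$reproducibility <= 1))
})

test_that("removing nothing reduces to plain reproducibility", {
  truth <- make_ground_truth(n_classes = 8, k_dims = 3, sparsity = 0.6,
                             seed = 130)
  tr <- simulate_trials(truth, n_trials = 20000,
                        workers = list(worker_profile("clean",
                                                      lapse_rate = 0.05)),
                        seed = 131)
  cfg <- fit_config(n_init_dims = 6, lambda = 0.2, max_epochs = 60,
                    patience = 8, seed = 132)
  ref <- fit_and_prune(tr, truth$images, cfg)$embedding
  out0 <- subset_stability(tr, truth$images, ref, cfg, removal = 0,
                           n_runs = 2, seed = 133)
  runs <- lapply(1:2, function(r) {
    c2 <- cfg; c2$seed <- spose2afc:::.child_seed(133, 10L + r)
    fit_and_prune(tr, truth$images, c2)$embedding
  })
  direct <- reproducibility(ref, runs)
  expect_equal(out0$table$reproducibility, direct$reproducibility)
  expect_equal(out0$trial_removal_fraction, 0)
})

test_that("targeted removal hurts a class-specific dimension most", {
  # build a truth with one dimension expressed only in two target classes
  set.seed(140)
  truth <- make_ground_truth(n_classes = 10, k_dims = 4, sparsity = 0.6,
                             seed = 140)
  W <- truth$embedding
  # expressed in classes 1-3 so it survives (weakened) targeted removal
  special <- truth$images$class_label %in% sprintf("class%03d", 1:3)
  W <- cbind(W, special * (0.8 + abs(rnorm(nrow(W), 0, 0.1))))
  colnames(W) <- sprintf("dim%d", 1:5)
  truth$embedding <- W
  tr <- simulate_trials(truth, n_trials = 12000,
                        workers = list(worker_profile("clean",
                                                      lapse_rate = 0.05)),
                        seed = 141)
  cfg <- fit_config(n_init_dims = 10, lambda = 0.2, max_epochs = 80,
                    patience = 8, seed = 142)
  targeted <- subset_stability(tr, truth$images, truth$embedding, cfg,
                               removal = c("class001", "class002"),
                               n_runs = 3, seed = 143)
  random <- subset_stability(tr, truth$images, truth$embedding, cfg,
                             removal = c("class007", "class008"),
                             n_runs = 3, seed = 143)
  # dimension 5 is the class-specific one (last column of the truth)
  r_targeted <- targeted$table$reproducibility[5]
  r_random <- random$table$reproducibility[5]
  expect_lt(r_targeted, r_random)
})
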