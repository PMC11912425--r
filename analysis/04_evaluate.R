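#!/usr/bin/env Rscript
# Stage 4: evaluate the embedding against behavior.
#
# Noise ceiling from the repeated-triplet subset, chance-corrected trial
# accuracy, probability-level agreement, within/between-class structure,
# few-shot SVM class decoding, semantic-matrix comparison, and the
# per-image dimension-pruning curve.

suppressPackageStartupMessages(library(spose2afc))

out <- "results/synthetic-study"
seed <- 20260924
images <- read.csv(file.path(out, "images.csv"), stringsAsFactors = FALSE)
emb <- read_embedding(file.path(out, "embedding.tsv"))
repeats <- read.csv(file.path(out, "repeats.csv"), stringsAsFactors = FALSE)
fit_meta <- jsonlite::read_json(file.path(out, "embedding.tsv.json"))

ceiling_pct <- as.numeric(consistency_ceiling(repeats))
acc_pct <- 100 * fit_meta$test_accuracy
cc <- chance_corrected(acc_pct, ceiling_pct)
agree <- choice_prob_agreement(emb, repeats)
cat(sprintf("ceiling %.2f%%, model %.2f%%, chance-corrected %.2f%%\n",
            ceiling_pct, acc_pct, cc))
cat(sprintf("choice-probability agreement: r = %.3f, accuracy %.2f%%\n",
            agree$r, agree$accuracy_pct))

sim_model <- read_similarity(file.path(out, "similarity_model.csv"))
wb <- within_between_class(sim_model, images)
cat(sprintf("within-class M = %.2f vs between M = %.2f, t(%d) = %.2f\n",
            wb$within_mean, wb$between_mean, wb$df, wb$t))

dec <- decode_classes(emb, images)
cat(sprintf(
  "decoding: pairwise %.2f%%, top-1 %.1f%%, top-5 %.1f%%, median rank %d\n",
  dec$pairwise_acc, dec$top1, dec$top5, as.integer(dec$median_rank)))

truth <- make_ground_truth(n_classes = 40, exemplars_per_class = 3,
                           k_dims = 6, sparsity = 0.4, seed = seed)
sem <- make_semantic_vectors(truth, coupling = 0.4, dim = 300,
                             seed = seed + 8)
semr <- semantic_comparison(sim_model, images, sem)
cat(sprintf("semantic comparison (coupling 0.4): R^2 = %.3f\n",
            semr$r_squared))

eval_trips <- simulate_trials(truth, n_trials = 20000, seed = seed + 9)
curve <- dimension_pruning_curve(emb, eval_trips)
write.csv(curve$curve, file.path(out, "pruning_curve.csv"),
          row.names = FALSE)
cat(sprintf("pruning: %d dims/image retain 95%%, %d retain 99%%\n",
            curve$dims_95, curve$dims_99))

report <- data.frame(
  ceiling_pct = ceiling_pct, model_accuracy_pct = acc_pct,
  chance_corrected_pct = cc, choice_prob_r = agree$r,
  choice_prob_accuracy_pct = agree$accuracy_pct,
  within_mean = wb$within_mean, between_mean = wb$between_mean,
  within_between_t = wb$t, pairwise_acc = dec$pairwise_acc,
  top1 = dec$top1, top5 = dec$top5, median_rank = dec$median_rank,
  semantic_r2 = semr$r_squared, dims_95 = curve$dims_95,
  dims_99 = curve$dims_99)
write.csv(report, file.path(out, "evaluation.csv"), row.names = FALSE)
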