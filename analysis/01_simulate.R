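#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Ground truth: 40 material classes x 3 exemplars (120 images) embedded in
# 6 sparse nonnegative dimensions. Behavior: 300k triplet 2-AFC trials from
# a worker population containing 80% clean responders (5% lapse), 10% fast
# responders and 10% position-biased responders, plus a repeated subset of
# 1,200 triplets sampled 60 times each for ceiling estimation, mirroring
# the canonical repeated-measures design.

suppressPackageStartupMessages(library(spose2afc))

out <- "results/synthetic-study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260924

truth <- make_ground_truth(n_classes = 40, exemplars_per_class = 3,
                           k_dims = 6, sparsity = 0.4, seed = seed)
write_embedding(truth$embedding, file.path(out, "ground_truth.tsv"))
write.csv(truth$images, file.path(out, "images.csv"), row.names = FALSE)

trials <- simulate_trials(
  truth, n_trials = 300000,
  workers = list(worker_profile("clean", lapse_rate = 0.05),
                 worker_profile("fast_responder"),
                 worker_profile("position_biased")),
  worker_fractions = c(0.8, 0.1, 0.1), n_workers = 1500, seed = seed + 1)
write.csv(trials, file.path(out, "trials_raw.csv"), row.names = FALSE)

repeats <- make_repeated_set(truth, n_triplets = 1200, m = 60,
                             lapse_rate = 0.05, seed = seed + 2)
write.csv(repeats, file.path(out, "repeats.csv"), row.names = FALSE)

qc <- exclude_workers(trials)
write.csv(qc$trials, file.path(out, "trials_clean.csv"), row.names = FALSE)
write.csv(qc$report, file.path(out, "qc_report.csv"), row.names = FALSE)

types <- attr(trials, "worker_types")
cat(sprintf(
  "simulated %d trials from %d workers (%d contaminated by construction)\n",
  nrow(trials), length(types), sum(types != "clean")))
cat(sprintf("QC excluded %d workers, %s of trials (Bayes accuracy %.2f%%)\n",
            nrow(qc$report), attr(qc$report, "pct_excluded"),
            attr(trials, "bayes_accuracy")))
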