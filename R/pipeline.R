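#' Run the synthetic end-to-end pipeline
#'
#' Executes simulate -> QC filter -> fit -> similarity reconstruction ->
#' evaluation (-> stability) from a single configuration list and writes all
#' artifacts (trial tables, embedding TSV + sidecar, similarity CSVs,
#' reports, resolved configuration, seeds, and the package version) into an
#' output directory.
#'
#' @param config Nested list with sections `simulate` (arguments of
#'   [make_ground_truth()] and [simulate_trials()]: `n_classes`,
#'   `exemplars_per_class`, `k_dims`, `sparsity`, `n_trials`, worker mixture
#'   fields `fast_fraction` / `biased_fraction`), `fit` (fields of
#'   [fit_config()] plus `prune_tol`), `evaluate` (`n_repeat_triplets`,
#'   `m_repeats`), optional `stability` (`removal`, `n_runs`), and a
#'   top-level `seed`.
#' @param out_dir Output directory (created if missing).
#' @return The output directory, invisibly; a machine-readable
#'   `summary.json` inside it holds the headline numbers.
#' @export
run_pipeline <- function(config, out_dir = tempfile("spose_run_")) {
  for (section in c("simulate", "fit", "evaluate")) {
    if (is.null(config[[section]]))
      stop("config is missing required section: ", section)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- config$simulate
  truth <- make_ground_truth(
    n_classes = sim$n_classes,
    exemplars_per_class = sim$exemplars_per_class %||% 3,
    k_dims = sim$k_dims, sparsity = sim$sparsity %||% 0.4,
    seed = .child_seed(seed, 1L))
  frac_fast <- sim$fast_fraction %||% 0
  frac_bias <- sim$biased_fraction %||% 0
  workers <- list(worker_profile("clean"))
  fracs <- 1 - frac_fast - frac_bias
  if (frac_fast > 0) { workers <- c(workers, list(worker_profile("fast_responder")))
    fracs <- c(fracs, frac_fast) }
  if (frac_bias > 0) { workers <- c(workers, list(worker_profile("position_biased")))
    fracs <- c(fracs, frac_bias) }
  trials <- simulate_trials(truth, n_trials = sim$n_trials,
                            workers = workers, worker_fractions = fracs,
                            seed = .child_seed(seed, 2L))
  utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  write_embedding(truth$embedding, file.path(out_dir, "ground_truth.tsv"))

  qc <- exclude_workers(trials)
  kept <- qc$trials

  fit_args <- config$fit
  prune_tol <- fit_args$prune_tol %||% 0.1
  fit_args$prune_tol <- NULL
  fit_args$seed <- fit_args$seed %||% .child_seed(seed, 3L)
  cfg <- do.call(fit_config, fit_args)
  fit <- fit_and_prune(kept, truth$images, cfg, prune_tol = prune_tol)
  write_embedding(fit, file.path(out_dir, "embedding.tsv"))

  sim_model <- marginal_similarity(fit$embedding)
  write_similarity(sim_model, file.path(out_dir, "similarity_model.csv"))

  ev <- config$evaluate
  repeats <- make_repeated_set(truth,
                               n_triplets = ev$n_repeat_triplets %||% 200,
                               m = ev$m_repeats %||% 20,
                               lapse_rate = ev$lapse_rate %||% 0.1,
                               seed = .child_seed(seed, 4L))
  report <- evaluation_report(fit$embedding, truth$images, repeats,
                              model_accuracy_pct = 100 * fit$test_accuracy,
                              seed = .child_seed(seed, 5L))

  stab <- NULL
  if (!is.null(config$stability)) {
    stab <- subset_stability(kept, truth$images, fit$embedding, cfg,
                             removal = config$stability$removal %||% 0.18,
                             n_runs = config$stability$n_runs %||% 3,
                             prune_tol = prune_tol,
                             seed = .child_seed(seed, 6L))
    utils::write.csv(stab$table, file.path(out_dir, "stability.csv"),
                     row.names = FALSE)
  }

  summary <- list(
    version = as.character(utils::packageVersion("spose2afc")),
    seed = seed,
    config = config,
    qc = list(n_excluded_trials = attr(qc$report, "n_excluded_trials"),
              pct_excluded = attr(qc$report, "pct_excluded")),
    fit = list(n_dims = ncol(fit$embedding), n_pruned = fit$n_pruned,
               test_accuracy = fit$test_accuracy,
               bayes_accuracy = attr(trials, "bayes_accuracy")),
    evaluation = unclass(report),
    stability = if (!is.null(stab))
      list(mean_reproducibility = stab$mean_reproducibility,
           trial_removal_fraction = stab$trial_removal_fraction))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
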