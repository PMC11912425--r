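# spose2afc

Sparse positive similarity embeddings from triplet 2-AFC judgments, in R.

## What this is for

Large-scale studies of perceptual similarity (e.g. of material images:
stone, silk, smoke, ...) collect millions of triplet two-alternative
forced-choice trials: a reference image on top, two options below, "which
option is more similar to the reference?". A full pairwise similarity
matrix for 600 images would need `3 * choose(600, 3) ≈ 107.46` million
trials, so instead one fits a model of the decision process to a sparse
sample of trials and reconstructs the rest.

`spose2afc` implements that entire analysis pipeline for researchers in
computational psychophysics:

* a **sparse positive similarity embedding** of the images: nonnegative
  vectors `x_i` fit to choices via the softmax rule
  `p(choose a) = exp(x_r·x_a) / (exp(x_r·x_a) + exp(x_r·x_b))`,
  trained by projected minibatch Adam (Rcpp core) with an L1 penalty,
  cross-validated penalty selection, pruning of near-zero dimensions and
  ordering by mean weight;
* **similarity reconstruction by marginalization**: `p(i,j)` = probability
  that `i` and `j` end up as the (reference, chosen) pair, averaged over
  all contexts `k` — exact enumeration up to ~700 images (the mean
  off-diagonal is provably 0.5 for any embedding, which the code reproduces
  to machine precision);
* **worker quality control** with the standard crowdsourcing rules
  (>25% of RTs under 600 ms or >50% under 900 ms at ≥60 trials; >60%
  one-position responses at ≥160 trials);
* the **evaluation battery**: intersubject noise ceiling from repeated
  triplets, chance-corrected accuracy, matrix agreement with Mantel
  randomization and bootstrap CI, split-half reliability with
  Spearman-Brown correction, within/between-class structure, few-shot
  linear-SVM class decoding, semantic-matrix comparison, per-image
  dimension-pruning curves;
* **stability analyses**: dimension reproducibility across random restarts
  (best-match correlations, Fisher-z averaged) and under category removal;
* an **image-computable stage**: ridge regression from image features to
  embedding dimensions with leave-one-material-out evaluation and nested
  CV, synthesizing similarity for novel images;
* a **synthetic-data generator** (ground-truth embeddings with class
  structure, simulated workers including fast responders and
  position-biased responders, repeated-triplet subsets, correlated
  semantic/feature vectors) so everything above is testable without any
  behavioral download.

## Worked example

The `analysis/` directory is a numbered, self-contained synthetic study
(40 classes x 3 exemplars, 6 true dimensions, 300k trials, contaminated
workers). Running it end to end:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_embedding.R
Rscript analysis/03_similarity.R
Rscript analysis/04_evaluate.R
Rscript analysis/05_stability.R
Rscript analysis/06_feature_model.R
Rscript analysis/07_map_and_clusters.R
```

prints, among other things:

```
simulated 300000 trials from 1500 workers (300 contaminated by construction)
QC excluded 303 workers, 20.20% of trials (Bayes accuracy 65.88%)
retained 6 of 30 dimensions (24 pruned) after 28 epochs
held-out trial accuracy 64.49%; mean best-match r to truth 0.985
model similarity: mean 0.500, SD 0.12, range 0.33-0.99
fully sampled subset: 205320 trials (60 images)
model vs behavior: r = 0.951 (95% CI 0.932-0.964, p = 0.0005)
split-half reliability 0.957; explainable variance captured 94.6%
ceiling 66.39%, model 64.49%, chance-corrected 88.40%
decoding: pairwise 99.36%, top-1 85.0%, top-5 100.0%, median rank 1
pruning: 5 dims/image retain 95%, 5 retain 99%
restart reproducibility: mean r = 0.982 (6/6 dims > 0.9)
removed 7 classes (44.1% of trials): mean r = 0.984 (drop -0.002)
leave-one-class-out dimension prediction: mean r = 0.974
```

Reading this: the fit recovers the 6 planted dimensions from 30 random
initial ones with near-perfect per-dimension correlations; its held-out
accuracy (64.5%) sits just under the generator's own Bayes ceiling (65.9%),
i.e. 88% of the way from chance to the intersubject consistency ceiling;
the reconstructed similarity matrix agrees with a fully sampled behavioral
matrix at r = 0.95 against a reliability bound of 0.96; and the dimensions
are stable across restarts and category subsets. All tables land in
`results/synthetic-study/`.

Each step is an exported function (`fit_embedding()`,
`marginal_similarity()`, `consistency_ceiling()`, `reproducibility()`,
`fit_ridge_maps()`, ...), and `run_pipeline(config)` drives the
simulate → filter → fit → reconstruct → evaluate chain from one
configuration list. See the methods vignette
(`vignettes/material-similarity-embeddings.Rmd`) for the model, estimator
definitions and design decisions.

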