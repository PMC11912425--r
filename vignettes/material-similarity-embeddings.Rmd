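---
title: "Sparse positive embeddings from triplet 2-AFC similarity judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse positive embeddings from triplet 2-AFC similarity judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spose2afc)
```

## The task and the model

In a triplet 2-AFC similarity trial a participant sees a reference image and
two option images and picks the option more similar to the reference. The
third image in each triplet acts as a *context*: it implicitly selects which
stimulus properties are relevant to the comparison, which is what makes
triplet judgments so much richer than direct pairwise ratings.

`spose2afc` models these choices with a sparse positive similarity embedding
(SPoSE-style): every image $i$ is a nonnegative vector $x_i \in
\mathbb{R}^k_{\ge 0}$, and the probability of choosing option $a$ over
option $b$ given reference $r$ is a softmax over reference-option dot
products,

$$
p(a \mid r; a, b) =
\frac{e^{x_r \cdot x_a}}{e^{x_r \cdot x_a} + e^{x_r \cdot x_b}},
$$

i.e. logistic in the dot-product difference. Three structural assumptions
give the dimensions their interpretability: **sparsity** (not every feature
is expressed in every material), **positivity** (a weight is the degree to
which a feature is expressed; there are no negative expressions), and
**continuity** (weights are graded, not binary).

Fitting minimizes the mean cross-entropy of observed choices plus an L1
penalty $\lambda \cdot \mathrm{mean}|W|$, subject to $W \ge 0$. Two choices
here deserve justification:

* **The penalty is on the *mean* absolute weight**, not the sum, so that a
  given $\lambda$ has comparable strength across image-set sizes and
  dimension counts. The consequence is that $\lambda$ values are on a
  different scale from formulations that penalize the sum: cross-validation
  on our synthetic 120-image / 300k-trial condition selects $\lambda \approx
  0.5$, and at 45 images / 60k trials $\approx 0.2$. The canonical
  full-scale behavioral dataset was fit elsewhere with a sum-scaled
  $\lambda = 0.0038$; the `fit_config()` default records that value but any
  new dataset should rerun `select_lambda()`.
* **Optimization** is minibatch Adam with projection onto the nonnegative
  orthant after *every* update, so nonnegativity is an invariant of the
  trajectory rather than a post-hoc clip. Defaults (learning rate 0.015,
  batch 256, patience 15) were chosen for robust convergence on synthetic
  data spanning 30-600 images; they are configuration, not science. Early
  stopping tracks the *full* objective evaluated with held-out
  cross-entropy (validation CE $+ \lambda\,\mathrm{mean}|W|$): tracking raw
  CE alone would reject the sparse solutions that a strong penalty is
  deliberately buying.

Initialization is half-normal (|N(0,1)|), seeded; the fit is bit-reproducible
given its seed (the shuffling runs on an internal Mersenne Twister rather
than R's RNG so the C++ hot loop is platform-stable).

After fitting, dimensions whose maximum weight falls below 10% of the global
maximum weight are pruned — a relative threshold, so the criterion survives
rescaling of the whole embedding — and the surviving
columns are ordered by mean weight across images, descending, with stable
ties.

## Similarity by marginalization over contexts

The similarity of images $i$ and $j$ is defined behaviorally: the
probability $p(i,j)$ that they end up as the (reference, chosen) pair,
averaged over every possible context $k$,

$$
p(i,j) = \frac{1}{n-2}\sum_{k \ne i,j}
\tfrac12\left[p(j \mid i; j,k) + p(i \mid j; i,k)\right].
$$

Only the two feasible reference assignments (reference $i$ or $j$)
contribute to $p(i,j)$; contexts where $k$ is the reference contribute to
$p(i,k)$ and $p(j,k)$ instead. Under this convention the three pair
probabilities inside any one context sum to $3/2$, which forces the mean
off-diagonal similarity to be exactly $0.5$ for *any* embedding — a
structural identity of the 2-AFC task that doubles as a sharp correctness
check on the implementation (`marginal_similarity()` reproduces it to
machine precision, and equals a scalar triple-loop oracle to $10^{-12}$).

Exact enumeration is vectorized per reference row and is comfortable up to
~700 images; a seeded sampled mode exists for larger stress tests and
reports its Monte-Carlo standard error. The empirical analogue
(`behavioral_similarity()`) averages observed choices within each
(pair, context) cell first and across contexts second, and flags — never
imputes — pairs that were never co-presented. The diagonal is set to 1 for
display and excluded from every statistic.

## Worker quality control

Crowdsourced triplet data need participant-level screening. A worker is
excluded iff

* at least 60 trials and (>25% of responses faster than 600 ms, or >50%
  faster than 900 ms), or
* at least 160 trials and >60% of responses at one of the two option
  positions.

All comparisons are strict, boundary workers are kept, and exclusion always
removes the worker's entire trial set. Workers with missing response times
are flagged "unfilterable" rather than passed silently; workers without
position records are exempt from the position rule (with a warning) but
remain subject to the RT rules. Filtering is idempotent and partitions the
trial set exactly — both are tested properties.

## Evaluation battery

**Noise ceiling.** From a repeated-triplet set (the study design samples
1,200 triplets 60 times each) the ceiling is the mean modal-response
fraction $\max(c_A, c_B)/m$. For finite $m$ this estimator sits slightly
*above* its asymptotic target $\mathbb{E}[\max(p, 1-p)]$ (the modal count of
a Binomial($m, p$) is upward-biased near $p = 0.5$, by roughly half a
percentage point at $m = 60$); the tests therefore check the simulated
ceiling against the exact finite-$m$ expectation computed from the binomial
law, not only against the asymptote.

**Chance-corrected accuracy** is $100\,(\text{acc} - 50)/(\text{ceiling} -
50)$ and is shift-invariant, undefined when the ceiling does not exceed
chance.

**Matrix agreement** between reconstructed and behavioral similarity uses
Pearson correlation on lower triangles, a Mantel-style randomization test
(joint row/column label permutations, 10,000 by default), and a bootstrap
over items for the confidence interval. **Split-half reliability** splits
trials within each unique triplet cell, correlates the two resulting
matrices, averages over random splits, and applies the Spearman-Brown
step-up $2r/(1+r)$. **Explainable variance** is reported as $100\,r^2 /
r_{\text{reliability}}$; the probability-level "predictive accuracy" is
implemented as $100$ minus the mean absolute deviation between predicted
and observed choice probabilities in percentage points. Both of these are
documented interpretations — the quantities are standard but their exact
published formulas are not printed anywhere — so they are reported alongside
the unambiguous Pearson correlations rather than asserted against published
values.

**Class structure.** Per class, mean within-exemplar similarity is compared
to the mean similarity of that class's exemplars to everything else, with a
paired $t$ across classes. **Decoding** trains a linear SVM on two exemplars
per class and tests on the third (all three folds); top-$k$ accuracy and the
median rank of the correct class come from one-vs-one vote counts, and
pairwise accuracy averages dedicated two-class SVMs over all class pairs
(the cost constant, default 1, is logged in the result). **Semantic
comparison** aggregates the similarity matrix to class level (mean of each
exemplar block) and correlates its lower triangle with the correlation
matrix of class-level semantic vectors.

**Dimension pruning curve.** Each image's smallest nonzero weight is zeroed
(simultaneously across images) and the squared correlation between pruned
and full-model choice probabilities on a fixed evaluation triplet set is
recorded, until every image retains one dimension. The curve is indexed by
the realized per-image dimension budget, so embeddings already sparser than
their column count report correct minimal counts; the headline outputs are
the smallest budgets preserving 95% and 99% of predictive variance.

## Stability

Reproducibility across restarts correlates each reference dimension with
every dimension of each refit and keeps the best match (greedy, per
reference dimension — two reference dimensions may legitimately claim the
same run dimension; a Hungarian one-to-one variant is available, padding
with NA when a run has fewer dimensions). Per-run correlations are averaged
after Fisher z-transformation, with $r$ clamped at $1 - 10^{-7}$ so
identical embeddings do not produce infinite $z$. Category-subset stability
removes whole classes (18% at random by default, or a targeted list), drops
every trial touching a removed image — on a fully sampled design the removed
fraction is exactly $1 - \binom{n-3m}{3}/\binom{n}{3}$, a tested
combinatorial identity — and refits with seeds derived from the master seed
by fixed offsets.

## The image-computable stage

Image feature vectors (deep-network activations in the original study;
synthetic mixtures here) are mapped to embedding dimensions by ridge
regression: one model per dimension, leave-one-material-out outer folds
(all exemplars of a class held out together, preventing exemplar leakage —
verified by a scramble test), nested inner CV over the penalty grid,
standardized features, intercept included. The solver is the closed-form
SVD ridge, which evaluates the entire penalty grid from one decomposition
and gives exact control over the grid (the lasso-oriented path solvers in
the installed stack reparameterize the penalty internally). Predictions are
clipped at zero to honor the embedding contract. For novel images the
per-dimension penalties chosen on the training set are reused.

One statistical artifact is worth knowing: with uninformative features the
held-out predictions are nearly constant per fold (the training mean
without the held-out class), which makes pooled held-out correlations
mildly *negative*, not zero — the familiar leave-one-group-out
anti-correlation. The null tests assert absence of positive signal rather
than exact zero.

## The synthetic-data generator

`make_ground_truth()` draws, per class, a Bernoulli(sparsity) support mask
and Gamma(2, 0.5) magnitudes (positive and right-skewed, like fitted sparse
embedding weights); exemplars add nonnegative half-normal noise *within the
class support* and are rescaled to the prototype norm, so exemplars of a
class share a support and correlate more with each other than across
classes. `simulate_trials()` draws contexts uniformly (or enumerates the
full design, three reference assignments per unordered triple), generates
choices from the softmax rule, flips them with the worker's lapse rate
(lapse 0.5 = fair coin), and attaches response times and screen positions
per worker profile: clean workers (log-normal RTs around 1.5 s), fast
responders (around 400 ms — caught by the RT rules), and position-biased
workers (90% of answers at a preferred position — caught by the position
rule). The generator reports its own Bayes accuracy, $\mathbb{E}[\max(p,
1-p)]$ under the noise-free model, the natural yardstick for any fit's
held-out accuracy. Every generator is a pure function of its seed.

What the generator does *not* emulate: real image content (features are
synthetic mixtures, not network activations), session effects and learning,
heterogeneous per-worker decision scales, and any semantic structure beyond
a linear coupling to class prototypes. Passing tests on synthetic data
therefore demonstrate the correctness and statistical behavior of the
pipeline, not the psychological claims about real material perception.

## Descriptive outputs

`cluster_dimensions()` clusters dimension profiles (average linkage on
Euclidean distances by default; both the linkage and the metric are
configurable since no single convention dominates the field) and summarizes
the dimension correlation matrix. `export_map()` runs exact t-SNE on
similarity-derived distances with classical-MDS initialization, dual
perplexities 5 and 30 (implemented by averaging the two symmetrized
affinity matrices, one reading of a dual-perplexity affinity), and 1,000
iterations; the learning rate follows the
$n/\text{exaggeration}$ heuristic so small and large maps are equally
stable.

## Problem sizes and numerical choices

The test suite and the bundled analysis chain run the study at a reduced,
self-contained scale chosen to exercise every code path in minutes on one
CPU: a 40-class x 3-exemplar truth with 6 dimensions and 300k trials for
fitting and stability (held-out accuracy lands within a few points of the
generator's Bayes accuracy; 30 initial dimensions prune back to 6), a
60-image fully sampled subset with two repeats (205,320 trials — the same
count as the canonical 60-image design) for matrix agreement and
reliability, and 1,200 x 60 repeated triplets for the ceiling. Degenerate
inputs are handled explicitly: all-zero embeddings prune to zero dimensions,
zero-variance dimensions are excluded from correlations with a warning,
never-sampled images stay near zero with a warning, and a non-finite
training loss aborts with diagnostics rather than returning garbage.

## Known limitations

Exact marginalization is quadratic in memory per reference row and cubic in
time overall; beyond ~700 images use the sampled mode. The SVM decoding
stage refits $\binom{c}{2}$ pairwise classifiers for the pairwise accuracy,
which is exhaustive but slow past a few hundred classes. The t-SNE
implementation is the exact $O(n^2)$ variant, adequate for hundreds of
images, not tens of thousands. The Hungarian matching variant reports NA
for reference dimensions that cannot be assigned when a refit retains fewer
dimensions; the greedy default never does.
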