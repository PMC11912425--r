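#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Minibatch Adam on the 2-AFC softmax choice model with an L1 penalty
// (lambda * mean absolute weight) and projection to the nonnegative
// orthant after every update.  All indices are 0-based on entry.
//
// Loss = mean_t CE(choice_t, sigmoid(x_r.x_a - x_r.x_b)) + lambda * mean |W|.
//
// Shuffling uses an internal mt19937 Fisher-Yates so that results are
// bit-reproducible for a given seed across platforms (std::shuffle is
// implementation-defined; R's RNG is kept out of the hot loop).

static inline double sigmoid(double z) {
  if (z >= 0) {
    return 1.0 / (1.0 + std::exp(-z));
  } else {
    double e = std::exp(z);
    return e / (1.0 + e);
  }
}

static void eval_set(const std::vector<double>& W, int K,
                     const IntegerVector& ref, const IntegerVector& oa,
                     const IntegerVector& ob, const IntegerVector& ya,
                     double& logloss, double& acc) {
  const int m = ref.size();
  double ll = 0.0; int correct = 0;
  for (int t = 0; t < m; ++t) {
    const double* xr = &W[(size_t)ref[t] * K];
    const double* xa = &W[(size_t)oa[t] * K];
    const double* xb = &W[(size_t)ob[t] * K];
    double sa = 0.0, sb = 0.0;
    for (int d = 0; d < K; ++d) { sa += xr[d] * xa[d]; sb += xr[d] * xb[d]; }
    double p = sigmoid(sa - sb);
    double y = ya[t];
    // clamp to avoid log(0) on saturated fits
    double pc = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
    ll += -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
    if ((p >= 0.5 ? 1.0 : 0.0) == y) ++correct;
  }
  logloss = m > 0 ? ll / m : NA_REAL;
  acc = m > 0 ? (double)correct / m : NA_REAL;
}

// [[Rcpp::export]]
List sgd_fit_core(NumericMatrix W0,
                  IntegerVector ref, IntegerVector oa, IntegerVector ob,
                  IntegerVector ya,
                  IntegerVector vref, IntegerVector voa, IntegerVector vob,
                  IntegerVector vya,
                  double lambda, double lr, int batch_size,
                  int max_epochs, int patience, int seed,
                  double adam_beta1, double adam_beta2, double adam_eps) {
  const int N = W0.nrow();
  const int K = W0.ncol();
  const int T = ref.size();
  const double nk = (double)N * (double)K;

  // row-major copy for cache-friendly triplet access
  std::vector<double> W((size_t)N * K);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < K; ++d)
      W[(size_t)i * K + d] = W0(i, d);

  std::vector<double> G((size_t)N * K, 0.0);
  std::vector<double> M((size_t)N * K, 0.0), V((size_t)N * K, 0.0);
  std::vector<double> Wbest = W;

  std::vector<int> order(T);
  for (int t = 0; t < T; ++t) order[t] = t;
  std::mt19937 rng((uint32_t)seed);

  std::vector<double> tr_loss, va_loss, va_acc;
  double best_val = R_PosInf;
  int best_epoch = -1, stale = 0, adam_t = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates
    for (int t = T - 1; t > 0; --t) {
      int j = (int)(rng() % (uint32_t)(t + 1));
      std::swap(order[t], order[j]);
    }
    double epoch_ce = 0.0;
    int nb = 0;
    for (int start = 0; start < T; start += batch_size) {
      int end = std::min(start + batch_size, T);
      int bs = end - start;
      std::fill(G.begin(), G.end(), 0.0);
      double batch_ce = 0.0;
      for (int u = start; u < end; ++u) {
        int t = order[u];
        int r = ref[t], a = oa[t], b = ob[t];
        double* xr = &W[(size_t)r * K];
        double* xa = &W[(size_t)a * K];
        double* xb = &W[(size_t)b * K];
        double sa = 0.0, sb = 0.0;
        for (int d = 0; d < K; ++d) { sa += xr[d] * xa[d]; sb += xr[d] * xb[d]; }
        double p = sigmoid(sa - sb);
        double y = ya[t];
        double g = (p - y) / bs;
        double pc = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
        batch_ce += -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
        double* gr = &G[(size_t)r * K];
        double* ga = &G[(size_t)a * K];
        double* gb = &G[(size_t)b * K];
        for (int d = 0; d < K; ++d) {
          gr[d] += g * (xa[d] - xb[d]);
          ga[d] += g * xr[d];
          gb[d] -= g * xr[d];
        }
      }
      if (!std::isfinite(batch_ce))
        stop("non-finite training loss at epoch %d; check data scaling", epoch + 1);
      epoch_ce += batch_ce;
      ++nb;
      // dense L1 subgradient (weights are nonnegative throughout)
      const double pen = lambda / nk;
      ++adam_t;
      const double bc1 = 1.0 - std::pow(adam_beta1, adam_t);
      const double bc2 = 1.0 - std::pow(adam_beta2, adam_t);
      for (size_t q = 0; q < W.size(); ++q) {
        double g = G[q] + pen;
        M[q] = adam_beta1 * M[q] + (1.0 - adam_beta1) * g;
        V[q] = adam_beta2 * V[q] + (1.0 - adam_beta2) * g * g;
        double step = lr * (M[q] / bc1) / (std::sqrt(V[q] / bc2) + adam_eps);
        double w = W[q] - step;
        W[q] = w > 0.0 ? w : 0.0;  // projection: nonnegativity after every step
      }
    }
    tr_loss.push_back(epoch_ce / T);

    double vll, vac;
    eval_set(W, K, vref, voa, vob, vya, vll, vac);
    va_loss.push_back(vll);
    va_acc.push_back(vac);

    // model selection on the full objective: held-out CE + L1 penalty
    double wsum = 0.0;
    for (size_t q = 0; q < W.size(); ++q) wsum += W[q];
    double pen_term = lambda * wsum / nk;
    double crit = (vref.size() > 0 ? vll : epoch_ce / T) + pen_term;
    if (crit < best_val - 1e-6) {
      best_val = crit;
      best_epoch = epoch;
      Wbest = W;
      stale = 0;
    } else if (++stale >= patience) {
      break;
    }
  }
  if (best_epoch < 0) { Wbest = W; best_epoch = (int)tr_loss.size() - 1; }

  NumericMatrix Wout(N, K);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < K; ++d)
      Wout(i, d) = Wbest[(size_t)i * K + d];

  return List::create(
    _["weights"] = Wout,
    _["train_loss"] = wrap(tr_loss),
    _["val_loss"] = wrap(va_loss),
    _["val_acc"] = wrap(va_acc),
    _["best_epoch"] = best_epoch + 1,
    _["n_epochs"] = (int)tr_loss.size());
}
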