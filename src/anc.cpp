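#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0.0) {
    double z = std::exp(-x);
    return 1.0 / (1.0 + z);
  }
  double z = std::exp(x);
  return z / (1.0 + z);
}

static inline double gain(double r, bool exp_gain) {
  return exp_gain ? std::exp2(r) - 1.0 : r;
}

// Ideal DCG: labels sorted descending, discount log2(position + 1).
static double ideal_dcg(const std::vector<double>& g) {
  std::vector<double> s(g);
  std::sort(s.begin(), s.end(), std::greater<double>());
  double out = 0.0;
  for (size_t p = 0; p < s.size(); ++p) {
    if (s[p] <= 0.0) break; // sorted: nothing positive remains
    out += s[p] / std::log2((double)p + 2.0);
  }
  return out;
}

// Batched Approximate-NDCG loss and analytic score gradient.
//
// Rows of S are per-case score vectors, rows of R the matching relevance
// labels. For each case:
//   pihat_i = 1 + sum_{j != i} sigma(alpha * (s_j - s_i))
//   loss    = -(1/idcg) * sum_i g(rel_i) / log2(1 + pihat_i)
// All-zero-label rows get loss 0 and zero gradient (the zero-ideal policy).
//
// Gradient: with c_i = dLoss/dpihat_i
//             = (g_i / idcg) / ((1 + pihat_i) * ln2 * log2(1 + pihat_i)^2)
// and A_ij = alpha * sigma'(alpha * (s_j - s_i))  (symmetric),
//   dLoss/ds_k = sum_{i != k} A_ik * (c_i - c_k).
// [[Rcpp::export]]
List anc_loss_grad_cpp(NumericMatrix S, NumericMatrix R, double alpha,
                       bool exp_gain, bool want_grad) {
  const int B = S.nrow(), n = S.ncol();
  if (R.nrow() != B || R.ncol() != n)
    stop("score and label matrices must have identical dimensions");
  const double ln2 = std::log(2.0);
  NumericVector loss(B);
  NumericMatrix grad(want_grad ? B : 1, want_grad ? n : 1);

  std::vector<double> g(n), pihat(n), c(n);
  std::vector<double> sig; // upper-triangle sigma(alpha*(s_j - s_i)), i < j
  if (want_grad) sig.resize((size_t)n * (n - 1) / 2);

  for (int b = 0; b < B; ++b) {
    bool any_pos = false;
    for (int i = 0; i < n; ++i) {
      g[i] = gain(R(b, i), exp_gain);
      if (g[i] > 0.0) any_pos = true;
      pihat[i] = 1.0;
    }
    if (!any_pos) { loss[b] = 0.0; continue; }
    const double idcg = ideal_dcg(g);

    size_t t = 0;
    for (int i = 0; i < n - 1; ++i) {
      const double si = S(b, i);
      for (int j = i + 1; j < n; ++j) {
        const double sg = sigmoid(alpha * (S(b, j) - si));
        pihat[i] += sg;
        pihat[j] += 1.0 - sg;
        if (want_grad) sig[t++] = sg;
      }
    }

    double l = 0.0;
    for (int i = 0; i < n; ++i) {
      const double lg = std::log2(1.0 + pihat[i]);
      l += g[i] / lg;
      if (want_grad)
        c[i] = (g[i] / idcg) / ((1.0 + pihat[i]) * ln2 * lg * lg);
    }
    loss[b] = -l / idcg;

    if (want_grad) {
      for (int i = 0; i < n; ++i) grad(b, i) = 0.0;
      t = 0;
      for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j) {
          const double sg = sig[t++];
          const double a = alpha * sg * (1.0 - sg);
          const double d = a * (c[j] - c[i]);
          grad(b, i) += d;
          grad(b, j) -= d;
        }
      }
    }
  }
  if (!want_grad) return List::create(_["loss"] = loss);
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
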