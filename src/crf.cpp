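// Linear-chain CRF: negative log-likelihood + gradient (forward-backward)
// and Viterbi decoding.  Parameters are a single flat vector:
//   state weights  W[attr * n_lab + lab]          (n_attr * n_lab entries)
//   transitions    T[from * n_lab + to]           (n_lab * n_lab entries)
// Sequences arrive flattened: tokens per sequence, attribute counts per
// token, attribute ids (0-based) and gold labels (0-based).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (double x : v) if (x > m) m = x;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List crf_nll_grad(NumericVector theta, int n_attr, int n_lab,
                  IntegerVector seq_lens, IntegerVector attr_counts,
                  IntegerVector attr_ids, IntegerVector labels) {
  const int trans_off = n_attr * n_lab;
  NumericVector grad(theta.size());
  double nll = 0.0;

  int tok0 = 0;   // global token index

  // per-token attribute start offsets (global)
  std::vector<int> astart(attr_counts.size() + 1);
  astart[0] = 0;
  for (int i = 0; i < attr_counts.size(); ++i)
    astart[i + 1] = astart[i] + attr_counts[i];

  for (int s = 0; s < seq_lens.size(); ++s) {
    const int T = seq_lens[s];
    if (T == 0) continue;
    // emission scores
    std::vector<double> sc((size_t)T * n_lab, 0.0);
    for (int t = 0; t < T; ++t) {
      const int g = tok0 + t;
      for (int a = astart[g]; a < astart[g + 1]; ++a) {
        const int base = attr_ids[a] * n_lab;
        for (int y = 0; y < n_lab; ++y) sc[(size_t)t * n_lab + y] += theta[base + y];
      }
    }
    // forward
    std::vector<double> alpha((size_t)T * n_lab);
    for (int y = 0; y < n_lab; ++y) alpha[y] = sc[y];
    std::vector<double> tmp(n_lab);
    for (int t = 1; t < T; ++t) {
      for (int y = 0; y < n_lab; ++y) {
        for (int x = 0; x < n_lab; ++x)
          tmp[x] = alpha[(size_t)(t - 1) * n_lab + x] + theta[trans_off + x * n_lab + y];
        alpha[(size_t)t * n_lab + y] = logsumexp(tmp) + sc[(size_t)t * n_lab + y];
      }
    }
    std::vector<double> last(n_lab);
    for (int y = 0; y < n_lab; ++y) last[y] = alpha[(size_t)(T - 1) * n_lab + y];
    const double logZ = logsumexp(last);
    // backward
    std::vector<double> beta((size_t)T * n_lab, 0.0);
    for (int t = T - 2; t >= 0; --t) {
      for (int x = 0; x < n_lab; ++x) {
        for (int y = 0; y < n_lab; ++y)
          tmp[y] = theta[trans_off + x * n_lab + y] + sc[(size_t)(t + 1) * n_lab + y]
                   + beta[(size_t)(t + 1) * n_lab + y];
        beta[(size_t)t * n_lab + x] = logsumexp(tmp);
      }
    }
    // gold score and observed counts
    double gold = 0.0;
    for (int t = 0; t < T; ++t) {
      const int g = tok0 + t;
      const int y = labels[g];
      gold += sc[(size_t)t * n_lab + y];
      for (int a = astart[g]; a < astart[g + 1]; ++a)
        grad[attr_ids[a] * n_lab + y] -= 1.0;
      if (t > 0) {
        const int x = labels[g - 1];
        gold += theta[trans_off + x * n_lab + y];
        grad[trans_off + x * n_lab + y] -= 1.0;
      }
    }
    nll += logZ - gold;
    // expected state counts
    for (int t = 0; t < T; ++t) {
      const int g = tok0 + t;
      for (int y = 0; y < n_lab; ++y) {
        const double p = std::exp(alpha[(size_t)t * n_lab + y]
                                  + beta[(size_t)t * n_lab + y] - logZ);
        if (p == 0.0) continue;
        for (int a = astart[g]; a < astart[g + 1]; ++a)
          grad[attr_ids[a] * n_lab + y] += p;
      }
    }
    // expected transition counts
    for (int t = 1; t < T; ++t) {
      for (int x = 0; x < n_lab; ++x) {
        const double ax = alpha[(size_t)(t - 1) * n_lab + x];
        for (int y = 0; y < n_lab; ++y) {
          const double p = std::exp(ax + theta[trans_off + x * n_lab + y]
                                    + sc[(size_t)t * n_lab + y]
                                    + beta[(size_t)t * n_lab + y] - logZ);
          grad[trans_off + x * n_lab + y] += p;
        }
      }
    }
    tok0 += T;

  }
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi(NumericVector theta, int n_attr, int n_lab,
                          IntegerVector attr_counts, IntegerVector attr_ids) {
  const int trans_off = n_attr * n_lab;
  const int T = attr_counts.size();
  IntegerVector out(T);
  if (T == 0) return out;
  std::vector<int> astart(T + 1);
  astart[0] = 0;
  for (int i = 0; i < T; ++i) astart[i + 1] = astart[i] + attr_counts[i];

  std::vector<double> sc((size_t)T * n_lab, 0.0);
  for (int t = 0; t < T; ++t)
    for (int a = astart[t]; a < astart[t + 1]; ++a) {
      const int base = attr_ids[a] * n_lab;
      for (int y = 0; y < n_lab; ++y) sc[(size_t)t * n_lab + y] += theta[base + y];
    }

  std::vector<double> delta((size_t)T * n_lab);
  std::vector<int> back((size_t)T * n_lab, 0);
  for (int y = 0; y < n_lab; ++y) delta[y] = sc[y];
  for (int t = 1; t < T; ++t) {
    for (int y = 0; y < n_lab; ++y) {
      double best = delta[(size_t)(t - 1) * n_lab] + theta[trans_off + y];
      int barg = 0;
      for (int x = 1; x < n_lab; ++x) {
        const double v = delta[(size_t)(t - 1) * n_lab + x]
                         + theta[trans_off + x * n_lab + y];
        if (v > best) { best = v; barg = x; }
      }
      delta[(size_t)t * n_lab + y] = best + sc[(size_t)t * n_lab + y];
      back[(size_t)t * n_lab + y] = barg;
    }
  }
  int y = 0;
  double best = delta[(size_t)(T - 1) * n_lab];
  for (int x = 1; x < n_lab; ++x)
    if (delta[(size_t)(T - 1) * n_lab + x] > best) {
      best = delta[(size_t)(T - 1) * n_lab + x];
      y = x;
    }
  out[T - 1] = y;
  for (int t = T - 1; t > 0; --t) {
    y = back[(size_t)t * n_lab + y];
    out[t - 1] = y;
  }
  return out;
}
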