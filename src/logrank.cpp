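// K-group log-rank (Mantel-Haenszel) chi-square, plus a permutation kernel.
// Inputs must be pre-sorted by time (ascending); labels are 0-based group
// codes. The permutation kernel draws from R's RNG so that set.seed() on
// the R side makes runs reproducible. The hot path avoids heap allocation:
// the observed-minus-expected sums and the hypergeometric covariance are
// accumulated in fixed buffers and the (K-1)-dimensional quadratic form is
// solved by Gaussian elimination with partial pivoting.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct LogrankWork {
  int n, K, nblocks;
  std::vector<int> block_start, block_end; // tied-time blocks
  std::vector<double> d_t;                 // total events per block
  std::vector<int> group_sizes;
  // scratch
  std::vector<double> atrisk, d_tk, O, E, V, A, u;
};

static void prepare_blocks(const NumericVector& time, const IntegerVector& event,
                           const IntegerVector& labels, int K, LogrankWork& w) {
  const int n = time.size();
  w.n = n; w.K = K;
  w.group_sizes.assign(K, 0);
  for (int i = 0; i < n; ++i) w.group_sizes[labels[i]]++;
  w.block_start.clear(); w.block_end.clear(); w.d_t.clear();
  int i = 0;
  while (i < n) {
    int j = i; double d = 0.0;
    while (j < n && time[j] == time[i]) { if (event[j] == 1) d += 1.0; ++j; }
    w.block_start.push_back(i); w.block_end.push_back(j); w.d_t.push_back(d);
    i = j;
  }
  w.nblocks = (int)w.block_start.size();
  w.atrisk.assign(K, 0.0); w.d_tk.assign(K, 0.0);
  w.O.assign(K, 0.0); w.E.assign(K, 0.0); w.V.assign(K * K, 0.0);
  w.A.assign((K - 1) * (K - 1), 0.0); w.u.assign(K - 1, 0.0);
}

// chi-square for the label configuration in `lab` (time-sorted order)
static double chi2_for_labels(const IntegerVector& event, const int* lab,
                              LogrankWork& w) {
  const int K = w.K;
  double n_at = w.n;
  for (int k = 0; k < K; ++k) {
    w.atrisk[k] = w.group_sizes[k];
    w.O[k] = 0.0; w.E[k] = 0.0;
  }
  std::fill(w.V.begin(), w.V.end(), 0.0);
  for (int b = 0; b < w.nblocks; ++b) {
    const int i0 = w.block_start[b], i1 = w.block_end[b];
    const double d = w.d_t[b];
    if (d > 0.0 && n_at > 0.0) {
      for (int k = 0; k < K; ++k) w.d_tk[k] = 0.0;
      for (int t = i0; t < i1; ++t) if (event[t] == 1) w.d_tk[lab[t]] += 1.0;
      const double inv = 1.0 / n_at;
      if (n_at > 1.0) {
        const double f = d * (n_at - d) / (n_at - 1.0);
        for (int k = 0; k < K; ++k) {
          const double pk = w.atrisk[k] * inv;
          w.O[k] += w.d_tk[k];
          w.E[k] += d * pk;
          for (int l = 0; l <= k; ++l) {
            const double pl = w.atrisk[l] * inv;
            w.V[k * K + l] += f * (((k == l) ? pk : 0.0) - pk * pl);
          }
        }
      } else {
        for (int k = 0; k < K; ++k) {
          w.O[k] += w.d_tk[k];
          w.E[k] += d * w.atrisk[k] * inv;
        }
      }
    }
    for (int t = i0; t < i1; ++t) { w.atrisk[lab[t]] -= 1.0; n_at -= 1.0; }
  }
  // quadratic form on the first K-1 groups
  const int m = K - 1;
  for (int k = 0; k < m; ++k) {
    w.u[k] = w.O[k] - w.E[k];
    for (int l = 0; l < m; ++l) {
      w.A[k * m + l] = (l <= k) ? w.V[k * K + l] : w.V[l * K + k];
    }
  }
  // solve A x = u in place, partial pivoting; near-singular pivots are
  // ridged by a tiny amount (degenerate configurations only)
  std::vector<double> x(w.u);
  std::vector<double> a(w.A);
  for (int c = 0; c < m; ++c) {
    int piv = c;
    for (int r = c + 1; r < m; ++r) {
      if (std::fabs(a[r * m + c]) > std::fabs(a[piv * m + c])) piv = r;
    }
    if (piv != c) {
      for (int cc = 0; cc < m; ++cc) std::swap(a[c * m + cc], a[piv * m + cc]);
      std::swap(x[c], x[piv]);
    }
    double p = a[c * m + c];
    if (std::fabs(p) < 1e-12) { p = (p >= 0 ? 1.0 : -1.0) * 1e-12; a[c * m + c] = p; }
    for (int r = c + 1; r < m; ++r) {
      const double fac = a[r * m + c] / p;
      if (fac == 0.0) continue;
      for (int cc = c; cc < m; ++cc) a[r * m + cc] -= fac * a[c * m + cc];
      x[r] -= fac * x[c];
    }
  }
  for (int c = m - 1; c >= 0; --c) {
    double s = x[c];
    for (int cc = c + 1; cc < m; ++cc) s -= a[c * m + cc] * x[cc];
    x[c] = s / a[c * m + c];
  }
  double chi2 = 0.0;
  for (int k = 0; k < m; ++k) chi2 += x[k] * w.u[k];
  return chi2 < 0.0 ? 0.0 : chi2;
}

// [[Rcpp::export]]
double logrank_chi2_cpp(NumericVector time, IntegerVector event,
                        IntegerVector labels, int K) {
  LogrankWork w;
  prepare_blocks(time, event, labels, K, w);
  std::vector<int> lab(labels.begin(), labels.end());
  return chi2_for_labels(event, lab.data(), w);
}

// [[Rcpp::export]]
NumericVector logrank_perm_cpp(NumericVector time, IntegerVector event,
                               IntegerVector labels, int K, int B) {
  LogrankWork w;
  prepare_blocks(time, event, labels, K, w);
  const int n = time.size();
  std::vector<int> lab(labels.begin(), labels.end());
  NumericVector out(B);
  GetRNGstate();
  for (int b = 0; b < B; ++b) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(lab[i], lab[j]);
    }
    out[b] = chi2_for_labels(event, lab.data(), w);
  }
  PutRNGstate();
  return out;
}
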