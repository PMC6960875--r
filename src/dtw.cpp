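#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Local cost between row i of A (n rows) and row j of B (m rows), both
// column-major with d channels. metric 0: Euclidean distance between rows;
// metric 1: quaternion cost 1 - |<a_i, b_j>| (rows are unit quaternions).
static inline double local_cost(const double *A, const double *B,
                                int n, int m, int d, int i, int j, int metric) {
  double acc = 0.0;
  if (metric == 1) {
    for (int k = 0; k < d; ++k) acc += A[(size_t)k * n + i] * B[(size_t)k * m + j];
    return 1.0 - std::fabs(acc);
  }
  for (int k = 0; k < d; ++k) {
    const double diff = A[(size_t)k * n + i] - B[(size_t)k * m + j];
    acc += diff * diff;
  }
  return std::sqrt(acc);
}

// Fill the accumulated-cost matrix D (n x m, row-major) for the DTW dynamic
// program with steps {(1,0),(0,1),(1,1)}.
static void fill_dp(const double *A, const double *B, int n, int m, int d,
                    int metric, std::vector<double> &D) {
  D[0] = local_cost(A, B, n, m, d, 0, 0, metric);
  for (int j = 1; j < m; ++j) D[j] = D[j - 1] + local_cost(A, B, n, m, d, 0, j, metric);
  for (int i = 1; i < n; ++i) {
    double *row = &D[(size_t)i * m];
    const double *prev = &D[(size_t)(i - 1) * m];
    row[0] = prev[0] + local_cost(A, B, n, m, d, i, 0, metric);
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (row[j - 1] < best) best = row[j - 1];
      row[j] = best + local_cost(A, B, n, m, d, i, j, metric);
    }
  }
}

// Backtrack the optimal warping path from (n-1, m-1). Preference order at
// ties: diagonal, then (i-1,j), then (i,j-1) -- fixed and deterministic.
static void backtrack(const std::vector<double> &D, int n, int m,
                      std::vector<int> &pi, std::vector<int> &pj) {
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      const double diag = D[(size_t)(i - 1) * m + (j - 1)];
      const double up   = D[(size_t)(i - 1) * m + j];
      const double left = D[(size_t)i * m + (j - 1)];
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    }
    pi.push_back(i); pj.push_back(j);
  }
}

// Normalized DTW: minimal accumulated cost divided by the optimal warping
// path length. Returns distance, accumulated cost, path length and (when
// requested) the path as 1-based index pairs from start to end.
// [[Rcpp::export]]
List cpp_dtw(NumericMatrix a, NumericMatrix b, int metric, bool want_path) {
  const int n = a.nrow(), m = b.nrow();
  if (n < 1 || m < 1) stop("DTW requires non-empty sequences");
  if (a.ncol() != b.ncol()) stop("sequences must have the same number of channels");
  const int d = a.ncol();

  std::vector<double> D((size_t)n * m);
  fill_dp(a.begin(), b.begin(), n, m, d, metric, D);
  std::vector<int> pi, pj;
  backtrack(D, n, m, pi, pj);
  const int plen = (int)pi.size();
  const double total = D[(size_t)n * m - 1];

  List out = List::create(_["distance"] = total / plen,
                          _["cost"] = total,
                          _["path_length"] = plen);
  if (want_path) {
    IntegerMatrix path(plen, 2);
    for (int k = 0; k < plen; ++k) {
      path(k, 0) = pi[plen - 1 - k] + 1;
      path(k, 1) = pj[plen - 1 - k] + 1;
    }
    out["path"] = path;
  }
  return out;
}

static double dtw_norm_dist(const NumericMatrix &a, const NumericMatrix &b,
                            int metric, std::vector<double> &D,
                            std::vector<int> &pi, std::vector<int> &pj) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  D.resize((size_t)n * m);
  fill_dp(a.begin(), b.begin(), n, m, d, metric, D);
  pi.clear(); pj.clear();
  backtrack(D, n, m, pi, pj);
  return D[(size_t)n * m - 1] / (double)pi.size();
}

// Symmetric matrix of normalized DTW distances between all pairs in a list
// of numeric matrices (used for medoid initialization of DBA).
// [[Rcpp::export]]
NumericMatrix cpp_dtw_pairwise(List seqs, int metric) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<NumericMatrix> mats;
  mats.reserve(n);
  for (int i = 0; i < n; ++i) mats.push_back(as<NumericMatrix>(seqs[i]));
  std::vector<double> D;
  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dist = dtw_norm_dist(mats[i], mats[j], metric, D, pi, pj);
      out(i, j) = dist;
      out(j, i) = dist;
    }
  }
  return out;
}

// Normalized DTW distances from one query to each template in a list.
// [[Rcpp::export]]
NumericVector cpp_dtw_to_templates(NumericMatrix query, List templates, int metric) {
  const int n = templates.size();
  NumericVector out(n);
  std::vector<double> D;
  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i) {
    NumericMatrix tpl = as<NumericMatrix>(templates[i]);
    out[i] = dtw_norm_dist(query, tpl, metric, D, pi, pj);
  }
  return out;
}
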