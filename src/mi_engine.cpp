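#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Plug-in mutual information (nats) from 1-based bin labels.
static double mi_from_bins(const int* xb, const int* yb, int n, int B,
                           std::vector<double>& joint,
                           std::vector<double>& px, std::vector<double>& py) {
  std::fill(joint.begin(), joint.end(), 0.0);
  std::fill(px.begin(), px.end(), 0.0);
  std::fill(py.begin(), py.end(), 0.0);
  for (int s = 0; s < n; ++s) {
    int i = xb[s] - 1, j = yb[s] - 1;
    joint[i * B + j] += 1.0;
    px[i] += 1.0;
    py[j] += 1.0;
  }
  double mi = 0.0;
  const double dn = (double)n;
  for (int i = 0; i < B; ++i) {
    for (int j = 0; j < B; ++j) {
      double c = joint[i * B + j];
      if (c > 0.0) mi += (c / dn) * std::log(c * dn / (px[i] * py[j]));
    }
  }
  return mi > 0.0 ? mi : 0.0;
}

static void copy_row(const IntegerMatrix& m, int row, std::vector<int>& out) {
  int n = m.ncol();
  for (int s = 0; s < n; ++s) out[s] = m(row, s);
}

// MI between every row of reg_bins and every row of tgt_bins.
// Both matrices hold 1-based equal-frequency bin labels, features x samples.
// [[Rcpp::export]]
NumericMatrix mi_cross_cpp(IntegerMatrix reg_bins, IntegerMatrix tgt_bins, int B) {
  int R = reg_bins.nrow(), T = tgt_bins.nrow(), n = reg_bins.ncol();
  if (tgt_bins.ncol() != n) stop("bin matrices must share the sample dimension");
  NumericMatrix out(R, T);
  std::vector<double> joint(B * B), px(B), py(B);
  std::vector<int> xb(n), yb(n);
  for (int r = 0; r < R; ++r) {
    copy_row(reg_bins, r, xb);
    for (int t = 0; t < T; ++t) {
      copy_row(tgt_bins, t, yb);
      out(r, t) = mi_from_bins(xb.data(), yb.data(), n, B, joint, px, py);
    }
  }
  return out;
}

// Precompute the permuted regulator bin vectors (contiguous, one per perm).
static std::vector<int> permuted_bins(const IntegerVector& reg_bin,
                                      const IntegerMatrix& perms) {
  int n = reg_bin.size(), P = perms.nrow();
  std::vector<int> xb_all((size_t)P * n);
  for (int p = 0; p < P; ++p) {
    int* dst = xb_all.data() + (size_t)p * n;
    for (int s = 0; s < n; ++s) dst[s] = reg_bin[perms(p, s) - 1];
  }
  return xb_all;
}

// For one regulator: count permutations whose MI against each target is
// >= the observed MI. perms holds 1-based sample orderings, one per row.
// [[Rcpp::export]]
IntegerVector mi_perm_counts_cpp(IntegerVector reg_bin, IntegerMatrix tgt_bins,
                                 int B, IntegerMatrix perms, NumericVector mi_obs) {
  int n = reg_bin.size(), T = tgt_bins.nrow(), P = perms.nrow();
  if (tgt_bins.ncol() != n || perms.ncol() != n || mi_obs.size() != T)
    stop("dimension mismatch in mi_perm_counts_cpp");
  std::vector<int> xb_all = permuted_bins(reg_bin, perms);
  IntegerVector counts(T);
  std::vector<double> joint(B * B), px(B), py(B);
  std::vector<int> yb(n);
  for (int t = 0; t < T; ++t) {
    copy_row(tgt_bins, t, yb);
    int c = 0;
    double obs = mi_obs[t];
    for (int p = 0; p < P; ++p) {
      double mi = mi_from_bins(xb_all.data() + (size_t)p * n, yb.data(), n, B,
                               joint, px, py);
      if (mi >= obs) ++c;
    }
    counts[t] = c;
  }
  return counts;
}

// Full permutation-null MI matrix (permutations x targets) for one regulator.
// [[Rcpp::export]]
NumericMatrix mi_perm_matrix_cpp(IntegerVector reg_bin, IntegerMatrix tgt_bins,
                                 int B, IntegerMatrix perms) {
  int n = reg_bin.size(), T = tgt_bins.nrow(), P = perms.nrow();
  if (tgt_bins.ncol() != n || perms.ncol() != n)
    stop("dimension mismatch in mi_perm_matrix_cpp");
  std::vector<int> xb_all = permuted_bins(reg_bin, perms);
  NumericMatrix out(P, T);
  std::vector<double> joint(B * B), px(B), py(B);
  std::vector<int> yb(n);
  for (int t = 0; t < T; ++t) {
    copy_row(tgt_bins, t, yb);
    for (int p = 0; p < P; ++p) {
      out(p, t) = mi_from_bins(xb_all.data() + (size_t)p * n, yb.data(), n, B,
                               joint, px, py);
    }
  }
  return out;
}
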