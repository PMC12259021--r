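#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pairwise NMI between discretized cell profiles.
//
// disc is genes x cells, entries in 0..n_bins-1. For a pair of cells (x, y)
// the marginal distributions p(x), p(y) are bin frequencies over the genes of
// each profile, the joint p(x,y) is the frequency of gene-aligned bin pairs,
// and
//   I(x,y)  = sum p(x,y) log[ p(x,y) / (p(x) p(y)) ]   (natural log)
//   NMI     = I / sqrt(H(x) H(y)),
// with NMI defined as 0 when either profile is constant (zero entropy).

static void marginal_counts(const IntegerMatrix& disc, int col, int n_bins,
                            std::vector<int>& out) {
  std::fill(out.begin(), out.end(), 0);
  const int L = disc.nrow();
  for (int g = 0; g < L; ++g) out[disc(g, col)]++;
}

static double entropy_from_counts(const std::vector<int>& cnt, int L) {
  double H = 0.0;
  for (size_t b = 0; b < cnt.size(); ++b) {
    if (cnt[b] > 0) {
      double p = (double)cnt[b] / L;
      H -= p * std::log(p);
    }
  }
  return H;
}

// NMI for one pair given precomputed marginal counts and entropies.
static double pair_nmi(const IntegerMatrix& disc, int i, int j, int n_bins,
                       const std::vector<int>& mi_cnt,
                       const std::vector<int>& mj_cnt,
                       double Hi, double Hj,
                       std::vector<int>& joint) {
  if (Hi <= 0.0 || Hj <= 0.0) return 0.0;
  const int L = disc.nrow();
  std::fill(joint.begin(), joint.end(), 0);
  for (int g = 0; g < L; ++g) joint[disc(g, i) * n_bins + disc(g, j)]++;
  double I = 0.0;
  for (int bx = 0; bx < n_bins; ++bx) {
    if (mi_cnt[bx] == 0) continue;
    for (int by = 0; by < n_bins; ++by) {
      int c = joint[bx * n_bins + by];
      if (c > 0) {
        // p log(p/(px py)) with p = c/L, px = mx/L, py = my/L
        I += ((double)c / L) *
             std::log(((double)c * L) / ((double)mi_cnt[bx] * mj_cnt[by]));
      }
    }
  }
  if (I < 0.0) I = 0.0;  // guard against round-off
  return I / std::sqrt(Hi * Hj);
}

// [[Rcpp::export]]
NumericVector cpp_pairwise_nmi(IntegerMatrix disc, int n_bins) {
  const int N = disc.ncol();
  std::vector<std::vector<int> > marg(N, std::vector<int>(n_bins));
  std::vector<double> H(N);
  const int L = disc.nrow();
  for (int i = 0; i < N; ++i) {
    marginal_counts(disc, i, n_bins, marg[i]);
    H[i] = entropy_from_counts(marg[i], L);
  }
  NumericVector out((R_xlen_t)N * (N - 1) / 2);
  std::vector<int> joint(n_bins * n_bins);
  R_xlen_t k = 0;
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j)
      out[k++] = pair_nmi(disc, i, j, n_bins, marg[i], marg[j], H[i], H[j], joint);
  return out;
}

static double median_inplace(std::vector<double>& v) {
  const size_t m = v.size();
  std::nth_element(v.begin(), v.begin() + m / 2, v.end());
  double hi = v[m / 2];
  if (m % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + m / 2);
  return 0.5 * (lo + hi);
}

// For each draw (row of idx, 1-based column indices into disc) compute all
// pairwise NMIs among the selected cells and return the median per draw.
// [[Rcpp::export]]
List cpp_draw_median_nmi(IntegerMatrix disc, IntegerMatrix idx, int n_bins) {
  const int N = disc.ncol();
  const int L = disc.nrow();
  const int n_draws = idx.nrow();
  const int n_cells = idx.ncol();

  // marginals/entropies once per cell, reused across draws
  std::vector<std::vector<int> > marg(N, std::vector<int>(n_bins));
  std::vector<double> H(N);
  for (int i = 0; i < N; ++i) {
    marginal_counts(disc, i, n_bins, marg[i]);
    H[i] = entropy_from_counts(marg[i], L);
  }

  NumericVector med(n_draws);
  R_xlen_t n_zero_entropy_pairs = 0;
  std::vector<int> joint(n_bins * n_bins);
  std::vector<double> vals((size_t)n_cells * (n_cells - 1) / 2);
  for (int d = 0; d < n_draws; ++d) {
    size_t k = 0;
    for (int a = 0; a < n_cells - 1; ++a) {
      int i = idx(d, a) - 1;
      for (int b = a + 1; b < n_cells; ++b) {
        int j = idx(d, b) - 1;
        if (H[i] <= 0.0 || H[j] <= 0.0) n_zero_entropy_pairs++;
        vals[k++] = pair_nmi(disc, i, j, n_bins, marg[i], marg[j], H[i], H[j], joint);
      }
    }
    med[d] = median_inplace(vals);
    if (d % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["medians"] = med,
                      _["n_zero_entropy_pairs"] = (double)n_zero_entropy_pairs);
}
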