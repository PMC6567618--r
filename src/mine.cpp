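#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Maximal information coefficient via the MINE approximation: one axis is
// equipartitioned, the other optimised by dynamic programming over clumps
// (maximal runs of x-consecutive points sharing a y-row). The grid budget is
// B = n^alpha; the number of clumps fed to the DP is capped at c * (max x
// bins) by merging into superclumps. Both axis orientations are scored and
// the elementwise maximum taken, as in the reference MINE procedure.

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

// Assign points to at most k rows, keeping tied values together and row
// sizes as even as possible. Returns rows actually used.
int equipartition(const std::vector<double>& v, const std::vector<int>& ord,
                  int k, std::vector<int>& row) {
  const int n = static_cast<int>(ord.size());
  int i = 0, curr = 0, rowsize = 0, assigned = 0;
  double share = static_cast<double>(n) / k;
  while (i < n) {
    int j = i;
    while (j < n && v[ord[j]] == v[ord[i]]) ++j;
    const int s = j - i;
    if (rowsize != 0 && curr < k - 1 &&
        std::fabs(rowsize + s - share) >= std::fabs(rowsize - share)) {
      ++curr;
      rowsize = 0;
      share = static_cast<double>(n - assigned) / (k - curr);
    }
    for (int t = i; t < j; ++t) row[ord[t]] = curr;
    rowsize += s;
    assigned += s;
    i = j;
  }
  return curr + 1;
}

// Entropy (natural log) of row counts.
double entropy(const std::vector<int>& counts, int n) {
  double h = 0.0;
  for (int c : counts)
    if (c > 0) {
      double p = static_cast<double>(c) / n;
      h -= p * std::log(p);
    }
  return h;
}

// Best normalised mutual information achievable for each x-bin count
// 2..lmax, given fixed y-rows; updates `cell` (index l-2).
void optimize_x_axis(const std::vector<double>& x, const std::vector<int>& ox,
                     const std::vector<int>& row, int nrows, int lmax,
                     double cdup, std::vector<double>& cell) {
  const int n = static_cast<int>(ox.size());

  // --- clumps: runs of x-consecutive points in one row; tied x forced together
  std::vector<int> clump_of(n);
  int cid = -1, prev_row = -2;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[ox[j]] == x[ox[i]]) ++j;
    bool pure = true;
    const int rr = row[ox[i]];
    for (int t = i + 1; t < j; ++t)
      if (row[ox[t]] != rr) {
        pure = false;
        break;
      }
    if (!(pure && rr == prev_row)) {
      ++cid;
      prev_row = pure ? rr : -3;
    }
    for (int t = i; t < j; ++t) clump_of[t] = cid; // position in x-order
    i = j;
  }
  int k = cid + 1;
  if (k < 2) return;

  std::vector<int> sz(k, 0);
  for (int t = 0; t < n; ++t) ++sz[clump_of[t]];

  // --- superclumps: cap clump count at c * lmax
  const int khat = std::max(2, static_cast<int>(cdup * lmax));
  std::vector<int> super_of(k);
  if (k > khat) {
    int cur = 0, acc = 0, assigned = 0;
    double share = static_cast<double>(n) / khat;
    for (int c0 = 0; c0 < k; ++c0) {
      if (acc != 0 && cur < khat - 1 &&
          std::fabs(acc + sz[c0] - share) >= std::fabs(acc - share)) {
        ++cur;
        acc = 0;
        share = static_cast<double>(n - assigned) / (khat - cur);
      }
      super_of[c0] = cur;
      acc += sz[c0];
      assigned += sz[c0];
    }
    k = cur + 1;
  } else {
    for (int c0 = 0; c0 < k; ++c0) super_of[c0] = c0;
  }

  // --- cumulative joint counts over clump prefixes
  // cum[t * nrows + q] = #points in clumps < t with row q; cnt[t] totals
  std::vector<int> cum(static_cast<size_t>(k + 1) * nrows, 0);
  std::vector<int> cnt(k + 1, 0);
  {
    std::vector<int> acc_row(nrows, 0);
    int acc_n = 0, pos = 0;
    for (int t = 0; t < k; ++t) {
      while (pos < n && super_of[clump_of[pos]] == t) {
        ++acc_row[row[ox[pos]]];
        ++acc_n;
        ++pos;
      }
      for (int q = 0; q < nrows; ++q) cum[(t + 1) * nrows + q] = acc_row[q];
      cnt[t + 1] = acc_n;
    }
  }

  // G(a,b) = sum_q c_q * log(c_q / c_tot) for the bin of clumps (a, b]
  // (so that sum over bins / n = -H(Q|P), and I = H(Q) - H(Q|P))
  auto G = [&](int a, int b) {
    const int ctot = cnt[b] - cnt[a];
    if (ctot <= 0) return 0.0;
    double g = 0.0;
    for (int q = 0; q < nrows; ++q) {
      const int cq = cum[b * nrows + q] - cum[a * nrows + q];
      if (cq > 0) g += cq * std::log(static_cast<double>(cq) / ctot);
    }
    return g;
  };
  std::vector<double> Gtab(static_cast<size_t>(k + 1) * (k + 1));
  for (int a = 0; a <= k; ++a)
    for (int b = a + 1; b <= k; ++b) Gtab[a * (k + 1) + b] = G(a, b);

  std::vector<int> qcounts(nrows, 0);
  for (int t = 0; t < n; ++t) ++qcounts[row[t] >= 0 ? row[t] : 0];
  // (row[] is indexed by original point id; recount properly)
  std::fill(qcounts.begin(), qcounts.end(), 0);
  for (int t = 0; t < n; ++t) ++qcounts[row[t]];
  const double hq = entropy(qcounts, n);

  const int leff = std::min(lmax, k);
  std::vector<double> Fprev(k + 1, NEG_INF), Fcur(k + 1, NEG_INF);
  for (int t = 1; t <= k; ++t) Fprev[t] = Gtab[t]; // l = 1: bin (0, t]
  for (int l = 2; l <= leff; ++l) {
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    for (int t = l; t <= k; ++t) {
      double best = NEG_INF;
      for (int s = l - 1; s < t; ++s) {
        const double v = Fprev[s] + Gtab[s * (k + 1) + t];
        if (v > best) best = v;
      }
      Fcur[t] = best;
    }
    const double info = hq + Fcur[k] / n;
    const double norm = std::log(static_cast<double>(std::min(l, nrows)));
    if (norm > 0.0) {
      double v = info / norm;
      if (v > 1.0) v = 1.0;
      if (v > cell[l - 2]) cell[l - 2] = v;
    }
    Fprev.swap(Fcur);
  }
}

double mic_pair(const std::vector<double>& x, const std::vector<double>& y,
                double alpha, double cpar) {
  const int n = static_cast<int>(x.size());
  if (n < 4) return NA_REAL;
  double B = std::pow(static_cast<double>(n), alpha);
  if (B < 4.0) B = 4.0;

  std::vector<int> ox(n), oy(n);
  for (int i = 0; i < n; ++i) ox[i] = oy[i] = i;
  std::sort(ox.begin(), ox.end(), [&](int a, int b) { return x[a] < x[b]; });
  std::sort(oy.begin(), oy.end(), [&](int a, int b) { return y[a] < y[b]; });
  if (x[ox[0]] == x[ox[n - 1]] || y[oy[0]] == y[oy[n - 1]]) return 0.0;

  double mic = 0.0;
  const int kymax = static_cast<int>(std::floor(B / 2.0));
  std::vector<int> row(n);
  for (int ori = 0; ori < 2; ++ori) {
    const std::vector<double>& xx = ori == 0 ? x : y;
    const std::vector<double>& yy = ori == 0 ? y : x;
    const std::vector<int>& oxx = ori == 0 ? ox : oy;
    const std::vector<int>& oyy = ori == 0 ? oy : ox;
    for (int ky = 2; ky <= kymax; ++ky) {
      const int lmax = static_cast<int>(std::floor(B / ky));
      if (lmax < 2) break;
      const int nrows = equipartition(yy, oyy, ky, row);
      if (nrows < 2) continue;
      std::vector<double> cell(lmax - 1, 0.0);
      optimize_x_axis(xx, oxx, row, nrows, lmax, cpar, cell);
      for (double v : cell)
        if (v > mic) mic = v;
    }
  }
  return mic;
}

} // namespace

// [[Rcpp::export(name = ".mic_pair_cpp")]]
double mic_pair_cpp(NumericVector x, NumericVector y, double alpha, double c) {
  if (x.size() != y.size()) stop("x and y must have equal length");
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  return mic_pair(xv, yv, alpha, c);
}

// X: samples x variables; returns symmetric MIC matrix with unit diagonal.
// [[Rcpp::export(name = ".mic_matrix_cpp")]]
NumericMatrix mic_matrix_cpp(NumericMatrix X, double alpha, double c) {
  const int p = X.ncol(), n = X.nrow();
  NumericMatrix S(p, p);
  std::vector<std::vector<double>> cols(p, std::vector<double>(n));
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) cols[j][i] = X(i, j);
  for (int a = 0; a < p; ++a) {
    S(a, a) = 1.0;
    for (int b = a + 1; b < p; ++b) {
      const double v = mic_pair(cols[a], cols[b], alpha, c);
      S(a, b) = v;
      S(b, a) = v;
    }
    Rcpp::checkUserInterrupt();
  }
  return S;
}
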