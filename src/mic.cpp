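// Maximal information coefficient (MIC) kernel.
//
// MIC(x, y) = max over grid shapes (nx, ny) with nx * ny <= B(n) of the
// maximal grid mutual information normalized by log2(min(nx, ny)).
//
// Two search strategies over grids:
//  * approx: the published heuristic — equipartition one axis into rows,
//    optimize the other axis by dynamic programming over clump boundaries
//    (at most c * ncols superclumps), applied in both orientations and
//    taking the max.
//  * exact: enumerate every admissible row partition (cuts between distinct
//    values) and run the exact column DP — feasible for small n; this is a
//    complete search over all grids, used so the small-n oracle-equality
//    invariants hold exactly.
//
// Ties: points with equal coordinate values can never be separated by a
// grid line, so they form atomic groups on each axis. Group tables and DP
// matrices live in flat, caller-owned buffers: the permutation tests call
// this kernel millions of times.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double LN2 = 0.6931471805599453;
static const double NEG = -1e100;

// p * log2(p), with 0 log 0 = 0
static inline double xlog2x(double p) {
  return p > 0.0 ? p * std::log(p) / LN2 : 0.0;
}

struct MicWork {
  std::vector<int> idx, row_of, rowcount, grows, gsize, mrows, msize,
      csum, pre, cut, row_of_rank;
  std::vector<double> sc, sr, rsorted, distinct, g, F, best;
};

// ---------- partition helpers ---------------------------------------------

// Equipartition values (sorted ascending) into ny rows, keeping ties
// together; writes the row of each sorted position into `row`.
static void equipartition(const std::vector<double>& v, int n, int ny,
                          std::vector<int>& row) {
  row.resize(n);
  int i = 0, curr = 0;
  double inrow = 0.0;
  double desired = (double)n / ny;
  while (i < n) {
    int j = i;
    while (j < n && v[j] == v[i]) ++j;
    int sz = j - i;
    if (inrow > 0.0 &&
        std::fabs(inrow + sz - desired) >= std::fabs(inrow - desired) &&
        curr < ny - 1) {
      ++curr;
      desired = (double)(n - i) / (ny - curr);
      inrow = 0.0;
    }
    for (int t = i; t < j; ++t) row[t] = curr;
    inrow += sz;
    i = j;
  }
}

// Column DP over k atomic groups with per-row counts grows[k x nr] and
// sizes gsize[k]. best[l] = max over partitions into l columns of
//   sum over columns of -(m/n) log2(m/n) + sum_r (m_r/n) log2(m_r/n)
// (so I(P;Q) = H(Q) + best[l]), for l = 1..lmax.
static void column_dp(MicWork& w, int k, int nr, int n, int lmax) {
  if (lmax > k) lmax = k;
  w.csum.assign(k + 1, 0);
  w.pre.assign((size_t)nr * (k + 1), 0);
  for (int t = 0; t < k; ++t) {
    w.csum[t + 1] = w.csum[t] + w.gsize[t];
    for (int r = 0; r < nr; ++r)
      w.pre[r * (k + 1) + t + 1] = w.pre[r * (k + 1) + t] +
        w.grows[(size_t)t * nr + r];
  }
  w.g.assign((size_t)(k + 1) * (k + 1), 0.0);
  for (int s = 0; s <= k; ++s)
    for (int t = s + 1; t <= k; ++t) {
      double m = w.csum[t] - w.csum[s];
      double val = -xlog2x(m / n);
      for (int r = 0; r < nr; ++r) {
        double mr = w.pre[r * (k + 1) + t] - w.pre[r * (k + 1) + s];
        val += xlog2x(mr / n);
      }
      w.g[(size_t)s * (k + 1) + t] = val;
    }
  w.F.assign((size_t)(k + 1) * (lmax + 1), NEG);
  for (int t = 1; t <= k; ++t)
    w.F[(size_t)t * (lmax + 1) + 1] = w.g[t];  // g[0*(k+1)+t]
  for (int l = 2; l <= lmax; ++l)
    for (int t = l; t <= k; ++t) {
      double mx = NEG;
      for (int s = l - 1; s < t; ++s) {
        double v = w.F[(size_t)s * (lmax + 1) + l - 1] +
          w.g[(size_t)s * (k + 1) + t];
        if (v > mx) mx = v;
      }
      w.F[(size_t)t * (lmax + 1) + l] = mx;
    }
  w.best.assign(lmax + 1, NEG);
  for (int l = 1; l <= lmax; ++l)
    w.best[l] = w.F[(size_t)k * (lmax + 1) + l];
}

// sort points by cv (stable on rv); fills w.sc (sorted column values) and
// w.sr (matching row values)
static void sort_points(MicWork& w, const std::vector<double>& cv,
                        const std::vector<double>& rv) {
  int n = (int)cv.size();
  w.idx.resize(n);
  for (int i = 0; i < n; ++i) w.idx[i] = i;
  std::sort(w.idx.begin(), w.idx.end(), [&](int a, int b) {
    if (cv[a] != cv[b]) return cv[a] < cv[b];
    if (rv[a] != rv[b]) return rv[a] < rv[b];
    return a < b;
  });
  w.sc.resize(n); w.sr.resize(n);
  for (int i = 0; i < n; ++i) {
    w.sc[i] = cv[w.idx[i]];
    w.sr[i] = rv[w.idx[i]];
  }
}

// Build atomic column-axis tie groups with per-row counts from w.sc and a
// per-point row assignment (w.row_of, in column order). Returns k.
static int atomic_groups(MicWork& w, int n, int nr) {
  w.grows.clear(); w.gsize.clear();
  int i = 0, k = 0;
  while (i < n) {
    int j = i;
    while (j < n && w.sc[j] == w.sc[i]) ++j;
    for (int r = 0; r < nr; ++r) w.grows.push_back(0);
    for (int t = i; t < j; ++t) w.grows[(size_t)k * nr + w.row_of[t]]++;
    w.gsize.push_back(j - i);
    ++k;
    i = j;
  }
  return k;
}

// Merge adjacent pure same-row groups (MINE clumps), then coalesce into at
// most kmax superclumps by size-equipartition. Rewrites w.grows/w.gsize via
// w.mrows/w.msize; returns new k.
static int clump_merge(MicWork& w, int k, int nr, int kmax) {
  w.mrows.clear(); w.msize.clear();
  int mk = 0;
  int last_pure = -2;  // pure row of the last merged group, -1 = mixed
  for (int t = 0; t < k; ++t) {
    int pr = -1;
    bool pure = true;
    for (int r = 0; r < nr; ++r)
      if (w.grows[(size_t)t * nr + r] > 0) {
        if (pr >= 0) { pure = false; break; }
        pr = r;
      }
    if (!pure) pr = -1;
    if (mk > 0 && pure && last_pure == pr) {
      w.mrows[(size_t)(mk - 1) * nr + pr] += w.gsize[t];
      w.msize[mk - 1] += w.gsize[t];
      continue;
    }
    for (int r = 0; r < nr; ++r)
      w.mrows.push_back(w.grows[(size_t)t * nr + r]);
    w.msize.push_back(w.gsize[t]);
    last_pure = pr;
    ++mk;
  }
  if (mk > kmax && kmax >= 2) {
    int n = 0;
    for (int t = 0; t < mk; ++t) n += w.msize[t];
    w.grows.clear(); w.gsize.clear();
    int sk = 0, placed = 0;
    double desired = (double)n / kmax, inrow = 0.0;
    for (int t = 0; t < mk; ++t) {
      int sz = w.msize[t];
      bool fresh = sk == 0 ||
        (inrow > 0.0 &&
         std::fabs(inrow + sz - desired) >= std::fabs(inrow - desired) &&
         sk < kmax);
      if (fresh) {
        for (int r = 0; r < nr; ++r) w.grows.push_back(0);
        w.gsize.push_back(0);
        ++sk;
        desired = (double)(n - placed) / std::max(1, kmax - sk + 1);
        inrow = 0.0;
      }
      for (int r = 0; r < nr; ++r)
        w.grows[(size_t)(sk - 1) * nr + r] += w.mrows[(size_t)t * nr + r];
      w.gsize[sk - 1] += sz;
      inrow += sz;
      placed += sz;
    }
    return sk;
  }
  w.grows.swap(w.mrows);
  w.gsize.swap(w.msize);
  return mk;
}

static double entropy_rows(const std::vector<int>& rowcount, int nr, int n) {
  double h = 0.0;
  for (int r = 0; r < nr; ++r) h -= xlog2x((double)rowcount[r] / n);
  return h;
}

// One orientation of the approx search: rows on rv (equipartitioned),
// columns on cv (DP-optimized). Updates mic in place.
static void approx_orientation(MicWork& w, const std::vector<double>& cv,
                               const std::vector<double>& rv,
                               double B, int cclump, double& mic) {
  int n = (int)cv.size();
  w.rsorted = rv;
  std::sort(w.rsorted.begin(), w.rsorted.end());
  sort_points(w, cv, rv);
  int nymax = (int)std::floor(B / 2.0);
  std::vector<int> rowS;
  for (int ny = 2; ny <= nymax; ++ny) {
    int cmax = (int)std::floor(B / ny);
    if (cmax < 2) break;
    equipartition(w.rsorted, n, ny, rowS);
    w.row_of.resize(n);
    w.rowcount.assign(ny, 0);
    for (int i = 0; i < n; ++i) {
      int pos = (int)(std::lower_bound(w.rsorted.begin(), w.rsorted.end(),
                                       w.sr[i]) - w.rsorted.begin());
      w.row_of[i] = rowS[pos];  // ties share a row by construction
      w.rowcount[rowS[pos]]++;
    }
    double HQ = entropy_rows(w.rowcount, ny, n);
    if (HQ <= 0.0) continue;
    int k = atomic_groups(w, n, ny);
    k = clump_merge(w, k, ny, cclump * cmax);
    column_dp(w, k, ny, n, cmax);
    for (int l = 2; l < (int)w.best.size(); ++l) {
      if (w.best[l] < -1e99) continue;
      double v = (HQ + w.best[l]) /
        (std::log((double)std::min(l, ny)) / LN2);
      if (v > mic) mic = v;
    }
  }
}

static double mic_approx(MicWork& w, const std::vector<double>& x,
                         const std::vector<double>& y,
                         double B, int cclump) {
  double mic = 0.0;
  approx_orientation(w, x, y, B, cclump, mic);  // rows on y, DP on x
  approx_orientation(w, y, x, B, cclump, mic);  // swapped
  return std::min(mic, 1.0);
}

// exact: enumerate all row partitions (cuts between distinct row values),
// exact column DP on atomic groups. Complete search over all grids.
static double mic_exact(MicWork& w, const std::vector<double>& x,
                        const std::vector<double>& y, double B) {
  int n = (int)x.size();
  double mic = 0.0;
  w.rsorted = y;
  std::sort(w.rsorted.begin(), w.rsorted.end());
  w.distinct.clear();
  for (int i = 0; i < n; ++i)
    if (w.distinct.empty() || w.rsorted[i] != w.distinct.back())
      w.distinct.push_back(w.rsorted[i]);
  int d = (int)w.distinct.size();
  if (d < 2) return 0.0;
  sort_points(w, x, y);
  int nymax = std::min(d, (int)std::floor(B / 2.0));
  for (int ny = 2; ny <= nymax; ++ny) {
    int cmax = (int)std::floor(B / ny);
    if (cmax < 2) break;
    w.cut.resize(ny - 1);
    for (int i = 0; i < ny - 1; ++i) w.cut[i] = i;
    bool more = true;
    while (more) {
      w.row_of_rank.resize(d);
      {
        int row = 0, ci = 0;
        for (int rk = 0; rk < d; ++rk) {
          w.row_of_rank[rk] = row;
          if (ci < ny - 1 && rk == w.cut[ci]) { ++row; ++ci; }
        }
      }
      w.row_of.resize(n);
      w.rowcount.assign(ny, 0);
      for (int i = 0; i < n; ++i) {
        int rk = (int)(std::lower_bound(w.distinct.begin(), w.distinct.end(),
                                        w.sr[i]) - w.distinct.begin());
        w.row_of[i] = w.row_of_rank[rk];
        w.rowcount[w.row_of[i]]++;
      }
      double HQ = entropy_rows(w.rowcount, ny, n);
      if (HQ > 0.0) {
        int k = atomic_groups(w, n, ny);
        column_dp(w, k, ny, n, cmax);
        for (int l = 2; l < (int)w.best.size(); ++l) {
          if (w.best[l] < -1e99) continue;
          double v = (HQ + w.best[l]) /
            (std::log((double)std::min(l, ny)) / LN2);
          if (v > mic) mic = v;
        }
      }
      // next combination of cut positions
      int i = ny - 2;
      while (i >= 0 && w.cut[i] == d - 1 - (ny - 1 - i)) --i;
      if (i < 0) more = false;
      else {
        ++w.cut[i];
        for (int j = i + 1; j < ny - 1; ++j) w.cut[j] = w.cut[j - 1] + 1;
      }
    }
  }
  return std::min(mic, 1.0);
}

static double mic_one(MicWork& w, const std::vector<double>& x,
                      const std::vector<double>& y,
                      double alpha, int cclump, double b_max, bool exact) {
  int n = (int)x.size();
  double B = b_max > 0 ? b_max : std::pow((double)n, alpha);
  if (B < 4.0) B = 4.0;
  bool cx = true, cy = true;
  for (int i = 1; i < n; ++i) {
    if (x[i] != x[0]) cx = false;
    if (y[i] != y[0]) cy = false;
  }
  if (cx || cy) return 0.0;
  return exact ? mic_exact(w, x, y, B) : mic_approx(w, x, y, B, cclump);
}

static std::vector<double> col_of(const NumericMatrix& m, int j) {
  std::vector<double> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = m(i, j);
  return v;
}

// Fisher-Yates using R's RNG so set.seed() governs reproducibility
static void shuffle_inplace(std::vector<double>& v) {
  int n = (int)v.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// [[Rcpp::export]]
double mic_cpp(NumericVector x, NumericVector y, double alpha, int cclump,
               double b_max, bool exact) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  MicWork w;
  return mic_one(w, xv, yv, alpha, cclump, b_max, exact);
}

// [[Rcpp::export]]
NumericVector mic_pairwise_cpp(NumericMatrix mat, IntegerVector ai,
                               IntegerVector bi, double alpha, int cclump,
                               double b_max, bool exact) {
  int np = ai.size();
  NumericVector out(np);
  MicWork w;
  for (int p = 0; p < np; ++p) {
    std::vector<double> a = col_of(mat, ai[p] - 1), b = col_of(mat, bi[p] - 1);
    out[p] = mic_one(w, a, b, alpha, cclump, b_max, exact);
  }
  return out;
}

// Permutation p-values: per replicate the first OTU's sample order is
// permuted relative to the second (equivalent in distribution to permuting
// both independently). p = (b + 1) / (n_perm + 1), b = # null MIC >= observed.
// [[Rcpp::export]]
NumericVector mic_perm_pvalues_cpp(NumericMatrix mat, IntegerVector ai,
                                   IntegerVector bi, double alpha, int cclump,
                                   int n_perm, bool exact) {
  RNGScope scope;
  int np = ai.size();
  NumericVector out(np);
  MicWork w;
  for (int p = 0; p < np; ++p) {
    std::vector<double> a = col_of(mat, ai[p] - 1), b = col_of(mat, bi[p] - 1);
    double obs = mic_one(w, a, b, alpha, cclump, -1.0, exact);
    int cnt = 0;
    std::vector<double> ap = a;
    for (int r = 0; r < n_perm; ++r) {
      shuffle_inplace(ap);
      if (mic_one(w, ap, b, alpha, cclump, -1.0, exact) >= obs - 1e-12) ++cnt;
    }
    out[p] = (cnt + 1.0) / (n_perm + 1.0);
  }
  return out;
}

// Null distribution of the edge-count statistic: number of unordered pairs
// with MIC > threshold, recomputed on tables where every OTU's sample order
// is permuted independently.
// [[Rcpp::export]]
List mic_null_edges_cpp(NumericMatrix mat, double alpha, int cclump,
                        double threshold, int n_perm, bool exact) {
  RNGScope scope;
  int pcols = mat.ncol();
  MicWork w;
  std::vector<std::vector<double> > cols(pcols);
  for (int j = 0; j < pcols; ++j) cols[j] = col_of(mat, j);
  auto count_edges = [&](const std::vector<std::vector<double> >& cs) {
    int cnt = 0;
    for (int a = 0; a < pcols; ++a)
      for (int b = a + 1; b < pcols; ++b)
        if (mic_one(w, cs[a], cs[b], alpha, cclump, -1.0, exact) > threshold)
          ++cnt;
    return cnt;
  };
  int observed = count_edges(cols);
  IntegerVector nulls(n_perm);
  int ge = 0;
  std::vector<std::vector<double> > perm = cols;
  for (int r = 0; r < n_perm; ++r) {
    for (int j = 0; j < pcols; ++j) shuffle_inplace(perm[j]);
    int c = count_edges(perm);
    nulls[r] = c;
    if (c >= observed) ++ge;
  }
  return List::create(_["observed"] = observed, _["b"] = ge,
                      _["null_counts"] = nulls,
                      _["p"] = (ge + 1.0) / (n_perm + 1.0));
}
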