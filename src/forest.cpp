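// Iterative random-forest imputation (missForest scheme) with the forest
// implemented from first principles: bagged regression trees, variance-
// reduction splits over ceil(p/3) candidate features, minimum leaf size
// given by the caller. A dedicated splitmix64 RNG keeps results bitwise
// reproducible for a given seed, independent of R's RNG state.
//
// The split search is engineered for the package's typical geometry (tens
// of rows, hundreds to thousands of columns): feature orderings are
// computed once per forest, node members are scattered into rank slots,
// candidate gains are compared by cross-multiplication (no divisions in
// the hot loop), and node member lists are partitioned in place.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, n); modulo bias is immaterial at these sizes
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Forest {
  // flattened node arrays across all trees; roots[t] indexes tree t's root
  std::vector<int> feat, left, right;
  std::vector<double> thr, val;
  std::vector<int> roots;

  int new_node() {
    feat.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    thr.push_back(0.0);
    val.push_back(0.0);
    return static_cast<int>(feat.size()) - 1;
  }

  double predict_mean(const std::vector<double>& x) const {
    double s = 0.0;
    for (size_t t = 0; t < roots.size(); ++t) {
      int node = roots[t];
      while (feat[node] >= 0) {
        node = (x[feat[node]] <= thr[node]) ? left[node] : right[node];
      }
      s += val[node];
    }
    return s / static_cast<double>(roots.size());
  }
};

// Training set: q features x ntr rows, column-major, with per-feature
// sorted values and row ranks computed once per forest.
struct TrainData {
  int ntr = 0, q = 0;
  std::vector<double> x;      // x[f * ntr + i]
  std::vector<double> y;
  std::vector<double> xsort;  // xsort[f * ntr + k], ascending
  std::vector<int> rank;      // rank[f * ntr + i] = position of row i

  void presort() {
    xsort.resize(x.size());
    rank.resize(x.size());
    std::vector<int> ord(ntr);
    for (int f = 0; f < q; ++f) {
      const double* xf = &x[static_cast<size_t>(f) * ntr];
      for (int i = 0; i < ntr; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(),
                       [xf](int a, int b) { return xf[a] < xf[b]; });
      double* xs = &xsort[static_cast<size_t>(f) * ntr];
      int* rk = &rank[static_cast<size_t>(f) * ntr];
      for (int k = 0; k < ntr; ++k) {
        xs[k] = xf[ord[k]];
        rk[ord[k]] = k;
      }
    }
  }
};

struct Workspace {
  std::vector<double> w, wy;         // bootstrap weight / weighted response
  std::vector<int> members;          // distinct bootstrap rows, partitioned in place
  std::vector<double> slot_w, slot_wy;  // rank-indexed scatter slots (zeroed)
  std::vector<double> xs, cw, cwy;   // compacted member stats in x-order
  std::vector<int> touched;
  std::vector<int> perm;

  void init(int ntr, int q) {
    w.assign(ntr, 0.0);
    wy.assign(ntr, 0.0);
    members.resize(ntr);
    slot_w.assign(ntr, 0.0);
    slot_wy.assign(ntr, 0.0);
    xs.resize(ntr);
    cw.resize(ntr);
    cwy.resize(ntr);
    touched.resize(ntr);
    perm.resize(q);
    for (int f = 0; f < q; ++f) perm[f] = f;
  }
};

class TreeGrower {
 public:
  TreeGrower(const TrainData& td, Forest& fo, Workspace& ws, Rng& rng,
             int mtry, int min_leaf)
      : td_(td), fo_(fo), ws_(ws), rng_(rng), mtry_(mtry), min_leaf_(min_leaf) {}

  void grow() {
    const int ntr = td_.ntr;
    std::fill(ws_.w.begin(), ws_.w.end(), 0.0);
    for (int i = 0; i < ntr; ++i) ws_.w[rng_.below(ntr)] += 1.0;
    int nm = 0;
    double W = 0.0, SY = 0.0;
    for (int i = 0; i < ntr; ++i) {
      if (ws_.w[i] > 0.0) {
        ws_.wy[i] = ws_.w[i] * td_.y[i];
        ws_.members[nm++] = i;
        W += ws_.w[i];
        SY += ws_.wy[i];
      }
    }
    const int root = fo_.new_node();
    fo_.roots.push_back(root);
    grow_node(root, 0, nm, W, SY);
  }

 private:
  void grow_node(int node, int begin, int end, double W, double SY) {
    if (W < 2.0 * min_leaf_ || end - begin < 2) {
      fo_.val[node] = SY / W;
      return;
    }
    // sample mtry candidate features (partial Fisher-Yates)
    for (int t = 0; t < mtry_; ++t) {
      const int j = t + rng_.below(td_.q - t);
      std::swap(ws_.perm[t], ws_.perm[j]);
    }
    double best_num = 0.0, best_den = 0.0, best_thr = 0.0;
    int best_f = -1;
    for (int t = 0; t < mtry_; ++t) {
      const int f = ws_.perm[t];
      const int* rk = &td_.rank[static_cast<size_t>(f) * td_.ntr];
      const double* xsrt = &td_.xsort[static_cast<size_t>(f) * td_.ntr];
      // scatter members into rank slots
      int lo = td_.ntr, hi = 0;
      for (int i = begin; i < end; ++i) {
        const int r = ws_.members[i];
        const int k = rk[r];
        ws_.slot_w[k] = ws_.w[r];
        ws_.slot_wy[k] = ws_.wy[r];
        ws_.touched[i - begin] = k;
        if (k < lo) lo = k;
        if (k > hi) hi = k;
      }
      // compact to x-sorted member arrays
      int m = 0;
      for (int k = lo; k <= hi; ++k) {
        const double c = ws_.slot_w[k];
        ws_.xs[m] = xsrt[k];
        ws_.cw[m] = c;
        ws_.cwy[m] = ws_.slot_wy[k];
        m += (c != 0.0);
      }
      for (int i = 0; i < end - begin; ++i) {
        const int k = ws_.touched[i];
        ws_.slot_w[k] = 0.0;
        ws_.slot_wy[k] = 0.0;
      }
      // best split: gains compared by cross-multiplication
      double swL = 0.0, syL = 0.0;
      for (int i = 0; i < m - 1; ++i) {
        swL += ws_.cw[i];
        syL += ws_.cwy[i];
        if (ws_.xs[i + 1] > ws_.xs[i] && swL >= min_leaf_ &&
            W - swL >= min_leaf_) {
          const double swR = W - swL;
          const double syR = SY - syL;
          const double num = syL * syL * swR + syR * syR * swL;
          const double den = swL * swR;
          const bool better = (best_f < 0) ? (num > 0.0)
                                           : (num * best_den > best_num * den);
          if (better) {
            best_num = num;
            best_den = den;
            best_f = f;
            best_thr = 0.5 * (ws_.xs[i] + ws_.xs[i + 1]);
          }
        }
      }
    }
    double improvement = -1.0;
    if (best_f >= 0) {
      improvement = best_num / best_den - SY * SY / W;
    }
    const double base = SY * SY / W;
    if (best_f < 0 || improvement <= 1e-12 * (std::fabs(base) + 1.0)) {
      fo_.val[node] = SY / W;
      return;
    }
    const double* xf = &td_.x[static_cast<size_t>(best_f) * td_.ntr];
    const double thr = best_thr;
    int* mbeg = &ws_.members[begin];
    int* mmid = std::stable_partition(mbeg, &ws_.members[end],
                                      [xf, thr](int r) { return xf[r] <= thr; });
    const int mid = begin + static_cast<int>(mmid - mbeg);
    double WL = 0.0, SYL = 0.0;
    for (int i = begin; i < mid; ++i) {
      WL += ws_.w[ws_.members[i]];
      SYL += ws_.wy[ws_.members[i]];
    }
    const int lnode = fo_.new_node();
    const int rnode = fo_.new_node();
    fo_.feat[node] = best_f;
    fo_.thr[node] = thr;
    fo_.left[node] = lnode;
    fo_.right[node] = rnode;
    grow_node(lnode, begin, mid, WL, SYL);
    grow_node(rnode, mid, end, W - WL, SY - SYL);
  }

  const TrainData& td_;
  Forest& fo_;
  Workspace& ws_;
  Rng& rng_;
  const int mtry_, min_leaf_;
};

Forest build_forest(const TrainData& td, int n_trees, int min_leaf, Rng& rng,
                    Workspace& ws) {
  Forest fo;
  const int mtry = (td.q + 2) / 3;  // ceil(q / 3) candidate features per split
  ws.init(td.ntr, td.q);
  TreeGrower grower(td, fo, ws, rng, mtry, min_leaf);
  for (int t = 0; t < n_trees; ++t) grower.grow();
  return fo;
}

}  // namespace

// [[Rcpp::export]]
List rf_missforest_impl(NumericMatrix X, int n_trees, int min_leaf,
                        int max_iter, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<char> miss(static_cast<size_t>(n) * p, 0);
  std::vector<char> row_has_miss(n, 0);
  std::vector<int> miss_count(p, 0);
  double grand_sum = 0.0;
  long grand_n = 0;
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      if (NumericMatrix::is_na(X(i, j))) {
        miss[static_cast<size_t>(j) * n + i] = 1;
        row_has_miss[i] = 1;
        miss_count[j]++;
      } else {
        grand_sum += X(i, j);
        grand_n++;
      }
    }
  }
  if (grand_n == 0) stop("matrix is entirely missing; nothing to learn from");
  const double grand_mean = grand_sum / grand_n;

  // completed working copy, initialised with column means
  NumericMatrix C = clone(X);
  for (int j = 0; j < p; ++j) {
    if (miss_count[j] == 0) continue;
    double s = 0.0;
    int m = 0;
    for (int i = 0; i < n; ++i) {
      if (!miss[static_cast<size_t>(j) * n + i]) {
        s += X(i, j);
        m++;
      }
    }
    const double mu = (m > 0) ? s / m : grand_mean;
    for (int i = 0; i < n; ++i) {
      if (miss[static_cast<size_t>(j) * n + i]) C(i, j) = mu;
    }
  }

  // incomplete columns, ascending missing count (ties toward lower index)
  std::vector<int> cols;
  for (int j = 0; j < p; ++j) {
    if (miss_count[j] > 0 && miss_count[j] < n) cols.push_back(j);
  }
  std::stable_sort(cols.begin(), cols.end(), [&](int a, int b) {
    return miss_count[a] < miss_count[b];
  });

  if (cols.empty()) {
    return List::create(_["imputed"] = C, _["n_iterations"] = 0,
                        _["converged"] = true);
  }

  // a column's forest never changes across passes when all of its training
  // rows are fully observed (their feature values are never re-imputed)
  std::vector<char> cacheable(p, 0);
  std::vector<Forest> cache(p);
  std::vector<char> cached(p, 0);
  for (size_t ci = 0; ci < cols.size(); ++ci) {
    const int j = cols[ci];
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      if (!miss[static_cast<size_t>(j) * n + i] && row_has_miss[i]) {
        ok = false;
        break;
      }
    }
    cacheable[j] = ok ? 1 : 0;
  }

  // all imputed cells, in a fixed order, for the stopping statistic
  std::vector<std::pair<int, int> > cells;  // (row, col)
  for (int j = 0; j < p; ++j) {
    if (miss_count[j] == n) continue;  // fully-missing column stays at fallback
    for (int i = 0; i < n; ++i) {
      if (miss[static_cast<size_t>(j) * n + i]) cells.push_back(std::make_pair(i, j));
    }
  }

  Rng rng(static_cast<uint64_t>(static_cast<int64_t>(seed)));
  TrainData td;
  Workspace ws;
  std::vector<double> old_vals(cells.size()), test_x;
  double prev_delta = 0.0;
  bool converged = false;
  int n_iter = 0;

  for (int pass = 1; pass <= max_iter; ++pass) {
    for (size_t c = 0; c < cells.size(); ++c) {
      old_vals[c] = C(cells[c].first, cells[c].second);
    }
    for (size_t ci = 0; ci < cols.size(); ++ci) {
      const int j = cols[ci];
      const int ntr = n - miss_count[j];
      const int q = p - 1;
      Forest* fo;
      if (cacheable[j] && cached[j]) {
        fo = &cache[j];
      } else {
        td.ntr = ntr;
        td.q = q;
        td.x.assign(static_cast<size_t>(q) * ntr, 0.0);
        td.y.resize(ntr);
        int r = 0;
        for (int i = 0; i < n; ++i) {
          if (miss[static_cast<size_t>(j) * n + i]) continue;
          td.y[r] = X(i, j);  // original observed response
          int f = 0;
          for (int jj = 0; jj < p; ++jj) {
            if (jj == j) continue;
            td.x[static_cast<size_t>(f) * ntr + r] = C(i, jj);
            f++;
          }
          r++;
        }
        td.presort();
        cache[j] = build_forest(td, n_trees, min_leaf, rng, ws);
        cached[j] = cacheable[j];
        fo = &cache[j];
      }
      test_x.resize(q);
      for (int i = 0; i < n; ++i) {
        if (!miss[static_cast<size_t>(j) * n + i]) continue;
        int f = 0;
        for (int jj = 0; jj < p; ++jj) {
          if (jj == j) continue;
          test_x[f++] = C(i, jj);
        }
        C(i, j) = fo->predict_mean(test_x);
      }
    }
    n_iter = pass;
    double num = 0.0, den = 0.0;
    for (size_t c = 0; c < cells.size(); ++c) {
      const double nv = C(cells[c].first, cells[c].second);
      const double d = nv - old_vals[c];
      num += d * d;
      den += nv * nv;
    }
    const double delta = (den > 0.0) ? num / den : 0.0;
    if (pass >= 2 && delta > prev_delta) {
      // criterion rose: return the previous pass's values
      for (size_t c = 0; c < cells.size(); ++c) {
        C(cells[c].first, cells[c].second) = old_vals[c];
      }
      converged = true;
      break;
    }
    if (delta == 0.0) {
      // exact fixed point: no imputed cell moved, so every later pass
      // would return these same values
      converged = true;
      break;
    }
    prev_delta = delta;
  }

  return List::create(_["imputed"] = C, _["n_iterations"] = n_iter,
                      _["converged"] = converged);
}
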