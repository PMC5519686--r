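// Random forest classifier: bagged CART trees with `mtry` candidate
// features per split and gini impurity. Deliberately small: dense
// feature matrices, a handful of features, n in the low hundreds.
// A self-contained implementation keeps the leave-one-out loop (n
// forests of 500 trees) fast enough for repeated simulation.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  // node arrays; leaf iff feature < 0, then `left` holds the class
  std::vector<int> feature, left, right;
  std::vector<double> thr;
  int add_node() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    thr.push_back(0.0);
    return (int)feature.size() - 1;
  }
  int predict(const double* x, int /*p*/) const {
    int node = 0;
    while (feature[node] >= 0)
      node = x[feature[node]] <= thr[node] ? left[node] : right[node];
    return left[node];
  }
};

struct Grower {
  const double* X;  // n x p, column major
  int n, p, K, mtry, min_node;
  std::mt19937* rng;
  std::vector<int> feat_pool;

  int majority(const std::vector<int>& idx, const int* y) {
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int best = 0;
    for (int k = 1; k < K; ++k) if (cnt[k] > cnt[best]) best = k;
    return best;
  }

  // returns node id
  int grow(Tree& t, std::vector<int>& idx, const int* y, int depth) {
    int node = t.add_node();
    bool pure = true;
    for (size_t i = 1; i < idx.size(); ++i)
      if (y[idx[i]] != y[idx[0]]) { pure = false; break; }
    if (pure || (int)idx.size() < std::max(2, min_node) || depth > 64) {
      t.feature[node] = -1;
      t.left[node] = majority(idx, y);
      return node;
    }
    // sample mtry features without replacement
    for (int i = 0; i < p; ++i) feat_pool[i] = i;
    for (int i = 0; i < mtry; ++i) {
      int j = i + (int)((*rng)() % (uint32_t)(p - i));
      std::swap(feat_pool[i], feat_pool[j]);
    }
    double best_gain = -1.0, best_thr = 0.0;
    int best_f = -1;
    std::vector<int> cnt_tot(K, 0);
    for (int i : idx) cnt_tot[y[i]]++;
    double nn = (double)idx.size();
    double imp_parent = 1.0;
    for (int k = 0; k < K; ++k) {
      double f = cnt_tot[k] / nn;
      imp_parent -= f * f;
    }
    std::vector<std::pair<double, int>> sv(idx.size());
    std::vector<int> cntl(K);
    for (int m = 0; m < mtry; ++m) {
      int f = feat_pool[m];
      const double* col = X + (size_t)f * n;
      for (size_t i = 0; i < idx.size(); ++i) sv[i] = {col[idx[i]], y[idx[i]]};
      std::sort(sv.begin(), sv.end());
      std::fill(cntl.begin(), cntl.end(), 0);
      int nl = 0;
      for (size_t i = 0; i + 1 < sv.size(); ++i) {
        cntl[sv[i].second]++; nl++;
        if (sv[i].first == sv[i + 1].first) continue;
        double nr = nn - nl;
        double gl = 1.0, gr = 1.0;
        for (int k = 0; k < K; ++k) {
          double fl = cntl[k] / (double)nl;
          double fr = (cnt_tot[k] - cntl[k]) / nr;
          gl -= fl * fl; gr -= fr * fr;
        }
        double gain = imp_parent - (nl / nn) * gl - (nr / nn) * gr;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (sv[i].first + sv[i + 1].first);
        }
      }
    }
    if (best_f < 0 || best_gain <= 1e-12) {
      t.feature[node] = -1;
      t.left[node] = majority(idx, y);
      return node;
    }
    std::vector<int> li, ri;
    const double* col = X + (size_t)best_f * n;
    for (int i : idx) (col[i] <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) {
      t.feature[node] = -1;
      t.left[node] = majority(idx, y);
      return node;
    }
    t.feature[node] = best_f;
    t.thr[node] = best_thr;
    int l = grow(t, li, y, depth + 1);
    int r = grow(t, ri, y, depth + 1);
    t.left[node] = l;
    t.right[node] = r;
    return node;
  }
};

// fit a forest on rows `rows` of X; each tree gets a bootstrap sample.
// inbag (optional, per tree) records which of `rows` were in the bag.
std::vector<Tree> fit_forest(const double* X, const int* y, int n, int p,
                             int K, const std::vector<int>& rows, int ntree,
                             int mtry, int min_node, std::mt19937& rng,
                             std::vector<std::vector<char>>* inbag = nullptr) {
  std::vector<Tree> forest(ntree);
  Grower g{X, n, p, K, mtry, min_node, &rng, std::vector<int>(p)};
  int m = (int)rows.size();
  std::vector<int> boot(m);
  for (int t = 0; t < ntree; ++t) {
    std::vector<char> bag(m, 0);
    for (int i = 0; i < m; ++i) {
      int j = (int)(rng() % (uint32_t)m);
      boot[i] = rows[j];
      bag[j] = 1;
    }
    std::vector<int> idx = boot;
    g.grow(forest[t], idx, y, 0);
    if (inbag) (*inbag)[t] = bag;
  }
  return forest;
}

}  // namespace

// Fit on (Xtr, ytr), return vote fractions for Xte rows. y is 0..K-1.
// [[Rcpp::export]]
NumericMatrix rf_fit_predict_cpp(NumericMatrix Xtr, IntegerVector ytr, int K,
                                 NumericMatrix Xte, int ntree, int mtry,
                                 int min_node, int seed) {
  int n = Xtr.nrow(), p = Xtr.ncol();
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  std::vector<int> y(ytr.begin(), ytr.end());
  std::vector<Tree> forest =
      fit_forest(REAL(Xtr), y.data(), n, p, K, rows, ntree, mtry, min_node, rng);
  int nt = Xte.nrow();
  NumericMatrix votes(nt, K);
  std::vector<double> x(p);
  for (int i = 0; i < nt; ++i) {
    for (int j = 0; j < p; ++j) x[j] = Xte(i, j);
    for (const Tree& t : forest) votes(i, t.predict(x.data(), p)) += 1.0;
    for (int k = 0; k < K; ++k) votes(i, k) /= ntree;
  }
  return votes;
}

// Leave-one-out cross-validation: for each row i a fresh forest is grown
// on the remaining rows and votes for row i are recorded.
// [[Rcpp::export]]
List rf_loocv_cpp(NumericMatrix X, IntegerVector yv, int K, int ntree,
                  int mtry, int min_node, int seed) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::vector<int> y(yv.begin(), yv.end());
  NumericMatrix votes(n, K);
  IntegerVector pred(n);
  std::vector<double> x(p);
  for (int i = 0; i < n; ++i) {
    std::mt19937 rng((uint32_t)seed + 7919u * (uint32_t)(i + 1));
    std::vector<int> rows;
    rows.reserve(n - 1);
    for (int j = 0; j < n; ++j)
      if (j != i) rows.push_back(j);
    std::vector<Tree> forest = fit_forest(REAL(X), y.data(), n, p, K, rows,
                                          ntree, mtry, min_node, rng);
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    for (const Tree& t : forest) votes(i, t.predict(x.data(), p)) += 1.0;
    int best = 0;
    for (int k = 1; k < K; ++k)
      if (votes(i, k) > votes(i, best)) best = k;
    pred[i] = best;
    for (int k = 0; k < K; ++k) votes(i, k) /= ntree;
  }
  return List::create(_["votes"] = votes, _["pred"] = pred);
}

// Out-of-bag permutation importance: mean per-tree decrease in OOB
// accuracy when one feature's values are shuffled, averaged over nrep
// shuffles. Also returns the forest's OOB accuracy.
// [[Rcpp::export]]
List rf_importance_cpp(NumericMatrix X, IntegerVector yv, int K, int ntree,
                       int mtry, int min_node, int seed, int nrep) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  std::vector<int> y(yv.begin(), yv.end());
  std::vector<std::vector<char>> inbag(ntree);
  std::vector<Tree> forest = fit_forest(REAL(X), y.data(), n, p, K, rows,
                                        ntree, mtry, min_node, rng, &inbag);
  std::vector<double> x(p);
  // OOB votes for accuracy
  NumericMatrix oob_votes(n, K);
  std::vector<int> noob(n, 0);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) {
      if (inbag[t][i]) continue;
      for (int j = 0; j < p; ++j) x[j] = X(i, j);
      oob_votes(i, forest[t].predict(x.data(), p)) += 1.0;
      noob[i]++;
    }
  }
  int ncls = 0, ok = 0;
  for (int i = 0; i < n; ++i) {
    if (noob[i] == 0) continue;
    int best = 0;
    for (int k = 1; k < K; ++k)
      if (oob_votes(i, k) > oob_votes(i, best)) best = k;
    ncls++;
    if (best == y[i]) ok++;
  }
  double oob_acc = ncls > 0 ? (double)ok / ncls : NA_REAL;

  NumericVector imp(p, 0.0);
  std::vector<int> oob_idx;
  std::vector<double> perm_col;
  for (int t = 0; t < ntree; ++t) {
    oob_idx.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[t][i]) oob_idx.push_back(i);
    if (oob_idx.empty()) continue;
    int m = (int)oob_idx.size();
    int base_ok = 0;
    for (int i : oob_idx) {
      for (int j = 0; j < p; ++j) x[j] = X(i, j);
      if (forest[t].predict(x.data(), p) == y[i]) base_ok++;
    }
    double base_acc = (double)base_ok / m;
    for (int f = 0; f < p; ++f) {
      double drop = 0.0;
      for (int r = 0; r < nrep; ++r) {
        perm_col.resize(m);
        for (int i = 0; i < m; ++i) perm_col[i] = X(oob_idx[i], f);
        for (int i = m - 1; i > 0; --i) {
          int j = (int)(rng() % (uint32_t)(i + 1));
          std::swap(perm_col[i], perm_col[j]);
        }
        int pok = 0;
        for (int i = 0; i < m; ++i) {
          for (int j = 0; j < p; ++j) x[j] = X(oob_idx[i], j);
          x[f] = perm_col[i];
          if (forest[t].predict(x.data(), p) == y[oob_idx[i]]) pok++;
        }
        drop += base_acc - (double)pok / m;
      }
      imp[f] += drop / nrep;
    }
  }
  for (int f = 0; f < p; ++f) imp[f] = imp[f] / ntree * 100.0;  // pct points
  return List::create(_["importance"] = imp, _["oob_accuracy"] = oob_acc,
                      _["oob_votes"] = oob_votes);
}
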