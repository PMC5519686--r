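// TFCE, connected components, and max-statistic permutation engines.
//
// Grids are flat vectors in R's column-major order with dims (nx, ny, nz);
// voxel v = i + nx*(j + ny*k).
//
// TFCE uses a single descending sweep over thresholds: voxels are
// activated as the threshold drops below their value and merged into an
// incremental union-find whose nodes carry an offset ("delta") relative
// to their parent, so every member of a component accumulates the
// component's extent^E * h^H * dh increments from the moment it joins,
// and merging components keep what they accumulated separately. This
// makes one TFCE evaluation roughly O(V * conn * alpha) instead of
// O(sum over thresholds of suprathreshold voxels).
//
// Threshold convention: h = dh, 2*dh, ..., floor(hmax/dh)*dh, and a voxel
// participates at h when value >= h (up to a tiny tolerance), so a lone
// voxel of height 1 with dh = 0.1, H = 2, E = 0.5 scores
// sum(h^2) * 0.1 = 0.385.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <functional>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct NeighborTable {
  std::vector<int> di, dj, dk, doff;  // doff relative linear offset
  NeighborTable(int conn, int nx, int ny) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          int l1 = std::abs(a) + std::abs(b) + std::abs(c);
          if (l1 == 0) continue;
          if (conn == 6 && l1 > 1) continue;
          if (conn == 18 && l1 > 2) continue;
          di.push_back(a); dj.push_back(b); dk.push_back(c);
          doff.push_back(a + nx * (b + ny * c));
        }
  }
  size_t size() const { return di.size(); }
};

// Incremental TFCE accumulator over one grid.
class TfceEngine {
 public:
  TfceEngine(int nx, int ny, int nz, int conn)
      : nx_(nx), ny_(ny), nz_(nz), V_(nx * ny * nz), nb_(conn, nx, ny),
        parent_(V_), size_(V_), delta_(V_), acc_(V_), active_(V_, 0),
        ix_(V_), iy_(V_), iz_(V_), powc_(V_ + 1) {
    int v = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++v) {
          ix_[v] = i; iy_[v] = j; iz_[v] = k;
        }
  }

  // vals: statistic per voxel (only masked voxels are passed in `order`,
  // sorted by decreasing value). Writes TFCE into out (full grid).
  void run(const std::vector<double>& vals, const std::vector<int>& order,
           double hmax, double H, double E, double dh,
           std::vector<double>& out) {
    if (order.empty() || hmax <= 0.0) return;
    double step = dh > 0.0 ? dh : hmax / 100.0;
    int nsteps = (int)std::floor(hmax / step + 1e-9);
    if (nsteps < 1) return;
    ++epoch_;
    roots_.clear();
    std::fill(powc_.begin(), powc_.end(), -1.0);
    const double tol = 1e-9 * step;
    size_t np = 0;
    for (int k = nsteps; k >= 1; --k) {
      double h = k * step;
      while (np < order.size() && vals[order[np]] >= h - tol) {
        activate(order[np], vals);
        ++np;
      }
      if (np == 0) continue;
      double inc_h = std::pow(h, H) * step;
      // lazy root list: drop entries that are no longer roots
      size_t w = 0;
      for (size_t r = 0; r < roots_.size(); ++r) {
        int v = roots_[r];
        if (parent_[v] != v) continue;
        roots_[w++] = v;
        double pe = powc_[size_[v]];
        if (pe < 0.0) pe = powc_[size_[v]] = std::pow((double)size_[v], E);
        acc_[v] += pe * inc_h;
      }
      roots_.resize(w);
    }
    for (size_t idx = 0; idx < np; ++idx) {
      int v = order[idx];
      double d = 0.0;
      int r = v;
      while (parent_[r] != r) { d += delta_[r]; r = parent_[r]; }
      out[v] = d + acc_[r];
    }
  }

 private:
  void activate(int v, const std::vector<double>& vals) {
    parent_[v] = v; size_[v] = 1; delta_[v] = 0.0; acc_[v] = 0.0;
    active_[v] = epoch_;
    roots_.push_back(v);
    int i = ix_[v], j = iy_[v], k = iz_[v];
    for (size_t m = 0; m < nb_.size(); ++m) {
      int ii = i + nb_.di[m];
      if (ii < 0 || ii >= nx_) continue;
      int jj = j + nb_.dj[m];
      if (jj < 0 || jj >= ny_) continue;
      int kk = k + nb_.dk[m];
      if (kk < 0 || kk >= nz_) continue;
      int u = v + nb_.doff[m];
      if (active_[u] == epoch_) unite(v, u);
    }
  }

  void unite(int a, int b) {
    int ra = find_full(a), rb = find_full(b);
    if (ra == rb) return;
    if (size_[ra] < size_[rb]) std::swap(ra, rb);
    delta_[rb] = acc_[rb] - acc_[ra];
    parent_[rb] = ra;
    size_[ra] += size_[rb];
  }

  // find with proper path compression of deltas
  int find_full(int v) {
    if (parent_[v] == v) return v;
    // collect path
    path_.clear();
    int r = v;
    while (parent_[r] != r) { path_.push_back(r); r = parent_[r]; }
    double d = 0.0;
    for (size_t i = path_.size(); i-- > 0;) {
      int u = path_[i];
      d += delta_[u];
      delta_[u] = d;
      parent_[u] = r;
    }
    return r;
  }

  int nx_, ny_, nz_, V_;
  NeighborTable nb_;
  std::vector<int> parent_, size_;
  std::vector<double> delta_, acc_;
  std::vector<uint32_t> active_;
  std::vector<int> ix_, iy_, iz_;
  std::vector<double> powc_;
  std::vector<int> roots_, path_;
  uint32_t epoch_ = 0;
};

inline void check_dims(const IntegerVector& dims, R_xlen_t n) {
  if (dims.size() != 3) stop("dims must have length 3");
  R_xlen_t v = (R_xlen_t)dims[0] * dims[1] * dims[2];
  if (v != n) stop("dims do not match grid length");
}

inline void check_conn(int conn) {
  if (conn != 6 && conn != 18 && conn != 26)
    stop("connectivity must be 6, 18 or 26");
}

// build the descending order of positive masked voxels; returns hmax
double build_order(const std::vector<double>& vals, const std::vector<char>& msk,
                   int V, std::vector<int>& order) {
  order.clear();
  double hmax = 0.0;
  for (int v = 0; v < V; ++v) {
    if (msk[v] && vals[v] > 0.0) {
      order.push_back(v);
      if (vals[v] > hmax) hmax = vals[v];
    }
  }
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return vals[a] > vals[b]; });
  return hmax;
}

}  // namespace

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       LogicalVector mask, double H, double E, double dh,
                       int conn) {
  check_dims(dims, stat.size());
  check_conn(conn);
  const int nx = dims[0], ny = dims[1], nz = dims[2], V = nx * ny * nz;
  std::vector<double> vals(V), out(V, 0.0);
  std::vector<char> msk(V);
  for (int v = 0; v < V; ++v) {
    msk[v] = mask[v] == TRUE;
    double x = stat[v];
    if (msk[v] && !R_finite(x)) stop("non-finite statistic inside mask");
    vals[v] = x;
  }
  TfceEngine eng(nx, ny, nz, conn);
  std::vector<int> order;
  order.reserve(V);
  double hmax = build_order(vals, msk, V, order);
  eng.run(vals, order, hmax, H, E, dh, out);
  return NumericVector(out.begin(), out.end());
}

// Connected components of a binary grid; labels numbered in decreasing
// component-size order, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector binary, IntegerVector dims,
                                   int conn) {
  check_dims(dims, binary.size());
  check_conn(conn);
  const int nx = dims[0], ny = dims[1], nz = dims[2], V = nx * ny * nz;
  NeighborTable nb(conn, nx, ny);
  std::vector<int> parent(V, -1), size(V, 0);
  std::function<int(int)> find = [&](int v) {
    int r = v;
    while (parent[r] != r) r = parent[r];
    while (parent[v] != r) { int nxt = parent[v]; parent[v] = r; v = nxt; }
    return r;
  };
  int v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        if (binary[v] != TRUE) continue;
        parent[v] = v; size[v] = 1;
        for (size_t m = 0; m < nb.size(); ++m) {
          int ii = i + nb.di[m], jj = j + nb.dj[m], kk = k + nb.dk[m];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          int u = v + nb.doff[m];
          if (parent[u] < 0) continue;
          int ra = find(v), rb = find(u);
          if (ra == rb) continue;
          if (size[ra] < size[rb]) std::swap(ra, rb);
          parent[rb] = ra;
          size[ra] += size[rb];
        }
      }
  std::vector<std::pair<int, int>> roots;  // (-size, root)
  for (int u = 0; u < V; ++u)
    if (parent[u] == u) roots.push_back({-size[u], u});
  std::sort(roots.begin(), roots.end());
  std::vector<int> root_label(V, 0);
  for (size_t r = 0; r < roots.size(); ++r) root_label[roots[r].second] = (int)r + 1;
  IntegerVector lab(V, 0);
  for (int u = 0; u < V; ++u)
    if (parent[u] >= 0) lab[u] = root_label[find(u)];
  return lab;
}

namespace {

// shared state for permutation engines: transposed data (subjects fastest)
struct PermData {
  int V, n;
  std::vector<double> Dt;     // n * V, voxel-major blocks
  std::vector<double> sum, sumsq;
  std::vector<char> msk;
  std::vector<int> mask_idx;

  PermData(const NumericMatrix& D, const LogicalVector& mask) {
    V = D.nrow(); n = D.ncol();
    Dt.resize((size_t)V * n);
    sum.assign(V, 0.0); sumsq.assign(V, 0.0);
    msk.resize(V);
    for (int v = 0; v < V; ++v) msk[v] = mask[v] == TRUE;
    for (int i = 0; i < n; ++i) {
      const double* col = &D(0, i);
      for (int v = 0; v < V; ++v) {
        double x = col[v];
        Dt[(size_t)v * n + i] = x;
        sum[v] += x;
        sumsq[v] += x * x;
      }
    }
    for (int v = 0; v < V; ++v)
      if (msk[v]) mask_idx.push_back(v);
  }
};

inline double t_from_moments(double m, double sumsq, int n) {
  double ss = sumsq - n * m * m;
  if (ss <= 1e-300) return m == 0.0 ? 0.0 : (m > 0 ? 1e6 : -1e6);
  double sd = std::sqrt(ss / (n - 1));
  return m / (sd / std::sqrt((double)n));
}

}  // namespace

// One-sample sign-flip permutation test with TFCE and max-statistic FWE
// correction. D is V x n (voxels x pairs). When n <= max_exhaustive (or
// 2^n <= P) all sign patterns are enumerated (identity included) and
// p = count / 2^n; otherwise the identity plus P random draws give
// p = (1 + #{null >= obs}) / (P + 1).
// [[Rcpp::export]]
List perm_signflip_cpp(NumericMatrix D, IntegerVector dims, LogicalVector mask,
                       double H, double E, double dh, int conn, int P,
                       int seed, int max_exhaustive) {
  check_dims(dims, D.nrow());
  check_conn(conn);
  const int nx = dims[0], ny = dims[1], nz = dims[2], V = nx * ny * nz;
  const int n = D.ncol();
  if (n < 2) stop("need at least 2 difference images");
  if (P < 1) stop("P must be positive");

  bool exhaustive = (n <= max_exhaustive) ||
                    (n <= 30 && (1LL << n) <= (long long)P);
  long long niter = exhaustive ? (1LL << n) : (long long)P + 1;

  PermData pd(D, mask);
  TfceEngine eng(nx, ny, nz, conn);
  std::vector<int> order; order.reserve(V);
  std::vector<double> tvals(V, 0.0), tf(V, 0.0), obs_t(V, 0.0), obs_tf(V, 0.0);
  std::vector<double> signs(n, 1.0);
  std::vector<double> maxdist;
  maxdist.reserve((size_t)niter);
  std::mt19937 rng((uint32_t)seed);

  for (long long p = 0; p < niter; ++p) {
    if (exhaustive) {
      for (int i = 0; i < n; ++i) signs[i] = ((p >> i) & 1LL) ? -1.0 : 1.0;
    } else if (p == 0) {
      std::fill(signs.begin(), signs.end(), 1.0);
    } else {
      for (int i = 0; i < n; ++i) signs[i] = (rng() & 1u) ? -1.0 : 1.0;
    }
    for (int v : pd.mask_idx) {
      const double* row = &pd.Dt[(size_t)v * n];
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += signs[i] * row[i];
      tvals[v] = t_from_moments(s / n, pd.sumsq[v], n);
    }
    double hmax = build_order(tvals, pd.msk, V, order);
    std::fill(tf.begin(), tf.end(), 0.0);
    eng.run(tvals, order, hmax, H, E, dh, tf);
    double mx = 0.0;
    for (int v : pd.mask_idx)
      if (tf[v] > mx) mx = tf[v];
    if (p == 0) { obs_t = tvals; obs_tf = tf; }
    if (exhaustive || p > 0) maxdist.push_back(mx);
  }

  std::vector<double> srt = maxdist;
  std::sort(srt.begin(), srt.end());
  NumericVector pmap(V, NA_REAL), tmap(V, NA_REAL), tfmap(V, NA_REAL);
  for (int v : pd.mask_idx) {
    double obs = obs_tf[v];
    long long cnt = srt.end() - std::lower_bound(srt.begin(), srt.end(), obs);
    double pv = exhaustive ? (double)cnt / (double)srt.size()
                           : (double)(1 + cnt) / (double)(P + 1);
    pmap[v] = pv > 1.0 ? 1.0 : pv;
    tmap[v] = obs_t[v];
    tfmap[v] = obs_tf[v];
  }
  return List::create(_["t"] = tmap, _["tfce"] = tfmap, _["p"] = pmap,
                      _["max_null"] = NumericVector(maxdist.begin(), maxdist.end()),
                      _["exhaustive"] = exhaustive,
                      _["n_perm"] = (double)(exhaustive ? niter : P));
}

// Two-sample (pooled variance) label-permutation test with TFCE and
// max-statistic FWE. group is 0/1 per column of D; the identity labeling
// provides the observed maps and p = (1 + #{null >= obs}) / (P + 1).
// [[Rcpp::export]]
List perm_labelperm_cpp(NumericMatrix D, IntegerVector group,
                        IntegerVector dims, LogicalVector mask,
                        double H, double E, double dh, int conn, int P,
                        int seed) {
  check_dims(dims, D.nrow());
  check_conn(conn);
  const int nx = dims[0], ny = dims[1], nz = dims[2], V = nx * ny * nz;
  const int n = D.ncol();
  if (group.size() != n) stop("group length must match columns");
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += group[i] == 1;
  int n0 = n - n1;
  if (n1 < 2 || n0 < 2) stop("need at least 2 subjects per group");
  if (P < 1) stop("P must be positive");

  PermData pd(D, mask);
  TfceEngine eng(nx, ny, nz, conn);
  std::vector<int> order; order.reserve(V);
  std::vector<double> tvals(V, 0.0), tf(V, 0.0), obs_t(V, 0.0), obs_tf(V, 0.0);
  std::vector<int> g(group.begin(), group.end()), idx1;
  idx1.reserve(n1);
  std::vector<double> maxdist;
  maxdist.reserve(P);
  std::mt19937 rng((uint32_t)seed);
  const double inv_n1 = 1.0 / n1, inv_n0 = 1.0 / n0;
  const double se_fac = std::sqrt(1.0 / n1 + 1.0 / n0);

  for (int p = 0; p <= P; ++p) {
    if (p > 0) {
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(rng() % (uint32_t)(i + 1));
        std::swap(g[i], g[j]);
      }
    }
    idx1.clear();
    for (int i = 0; i < n; ++i)
      if (g[i] == 1) idx1.push_back(i);
    for (int v : pd.mask_idx) {
      const double* row = &pd.Dt[(size_t)v * n];
      double s1 = 0.0;
      for (int i : idx1) s1 += row[i];
      double m1 = s1 * inv_n1;
      double m0 = (pd.sum[v] - s1) * inv_n0;
      double ss = pd.sumsq[v] - n1 * m1 * m1 - n0 * m0 * m0;
      if (ss <= 1e-300) {
        tvals[v] = (m1 == m0) ? 0.0 : (m1 > m0 ? 1e6 : -1e6);
      } else {
        double sp = std::sqrt(ss / (n - 2));
        tvals[v] = (m1 - m0) / (sp * se_fac);
      }
    }
    double hmax = build_order(tvals, pd.msk, V, order);
    std::fill(tf.begin(), tf.end(), 0.0);
    eng.run(tvals, order, hmax, H, E, dh, tf);
    double mx = 0.0;
    for (int v : pd.mask_idx)
      if (tf[v] > mx) mx = tf[v];
    if (p == 0) { obs_t = tvals; obs_tf = tf; }
    else maxdist.push_back(mx);
  }

  std::vector<double> srt = maxdist;
  std::sort(srt.begin(), srt.end());
  NumericVector pmap(V, NA_REAL), tmap(V, NA_REAL), tfmap(V, NA_REAL);
  for (int v : pd.mask_idx) {
    double obs = obs_tf[v];
    long long cnt = srt.end() - std::lower_bound(srt.begin(), srt.end(), obs);
    double pv = (double)(1 + cnt) / (double)(P + 1);
    pmap[v] = pv > 1.0 ? 1.0 : pv;
    tmap[v] = obs_t[v];
    tfmap[v] = obs_tf[v];
  }
  return List::create(_["t"] = tmap, _["tfce"] = tfmap, _["p"] = pmap,
                      _["max_null"] = NumericVector(maxdist.begin(), maxdist.end()),
                      _["exhaustive"] = false, _["n_perm"] = (double)P);
}
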