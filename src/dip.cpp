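#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

// Hartigan dip statistic: the minimum over all unimodal distribution
// functions G (convex on (-inf, m], concave on [m, inf), an atom at the
// mode allowed) of sup_x |F_n(x) - G(x)|.
//
// For unique sorted values u_0 < ... < u_{m-1} with lower/upper cdf
// corners lc_j, uc_j, a candidate mode atom at u_k splits G into a convex
// piece on u_0..u_k (band: within d of both corners at interior points,
// of lc only at u_k) and a concave piece on u_k..u_{m-1} (band: within d
// of uc only at u_k), joined monotonically: a_k <= b_k.
//
// Feasibility of a given d for split k requires
//   (i)  the convex band is consistent: the largest "triple violation"
//        dl(k) = max_{i<k} ( uc_i - GCM_k(u_i) ) <= 2d, where GCM_k is
//        the greatest convex minorant of the lower corners on 0..k
//        (mirrored condition du(k) on the right), and
//   (ii) the smallest junction value reachable by a convex in-band piece,
//        fL_k(d), does not exceed the largest value reachable by the
//        concave piece, gR_k(d).
// Convexity propagates chord slopes: for any i1 < i2 < k,
//   a_k >= (uc_{i2} - d) + s * (u_k - u_{i2}),
//   s = max(0, ((uc_{i2} - d) - (lc_{i1} + d)) / (u_{i2} - u_{i1})),
// together with a_k >= lc_k - d; fL_k(d) is the max of these lower
// bounds (achievable: the upper envelope of the bounding lines is convex,
// monotone, and stays inside the band once (i) holds). gR is the mirror
// image. All bounds relax monotonically in d, so the dip is found by
// bisection; per evaluation, the best i1 for each i2 is a tangent to the
// incremental lower hull of the (u, lc) points, and the envelope of the
// bounding lines is queried with a Li Chao tree over the fixed grid.

namespace {

struct LiChao {
  // max-envelope of lines over fixed query coordinates xs
  int n;
  const std::vector<double>* xs;
  std::vector<double> slope, icpt;
  std::vector<bool> has;
  void init(const std::vector<double>* coords) {
    xs = coords;
    n = (int)coords->size();
    slope.assign(4 * n + 4, 0.0);
    icpt.assign(4 * n + 4, 0.0);
    has.assign(4 * n + 4, false);
  }
  double val(double a, double b, int i) const {
    return a * (*xs)[i] + b;
  }
  void insert(double a, double b, int node, int lo, int hi) {
    if (lo > hi) return;
    int mid = (lo + hi) / 2;
    if (!has[node]) {
      has[node] = true; slope[node] = a; icpt[node] = b;
      return;
    }
    bool left_better = val(a, b, lo) > val(slope[node], icpt[node], lo);
    bool mid_better = val(a, b, mid) > val(slope[node], icpt[node], mid);
    if (mid_better) {
      std::swap(a, slope[node]);
      std::swap(b, icpt[node]);
    }
    if (lo == hi) return;
    if (left_better != mid_better) insert(a, b, 2 * node, lo, mid);
    else insert(a, b, 2 * node + 1, mid + 1, hi);
  }
  void add(double a, double b) { insert(a, b, 1, 0, n - 1); }
  double query(int i, int node, int lo, int hi) const {
    double best = -1e300;
    while (true) {
      if (has[node]) best = std::max(best, val(slope[node], icpt[node], i));
      if (lo == hi) break;
      int mid = (lo + hi) / 2;
      if (i <= mid) { node = 2 * node; hi = mid; }
      else { node = 2 * node + 1; lo = mid + 1; }
    }
    return best;
  }
  double query(int i) const { return query(i, 1, 0, n - 1); }
};

// Incremental lower convex hull of points (x_i, y_i), x strictly
// increasing, supporting max-slope tangent queries from a point to its
// right.
struct LowerHull {
  std::vector<double> hx, hy;
  void add(double x, double y) {
    while (hx.size() >= 2) {
      size_t s = hx.size();
      double cross = (hx[s - 1] - hx[s - 2]) * (y - hy[s - 1]) -
                     (x - hx[s - 1]) * (hy[s - 1] - hy[s - 2]);
      if (cross <= 0) { hx.pop_back(); hy.pop_back(); } else break;
    }
    hx.push_back(x);
    hy.push_back(y);
  }
  // max over hull points Q of (py - Q.y) / (px - Q.x), px > all Q.x
  double max_slope(double px, double py) const {
    if (hx.empty()) return -1e300;
    int lo = 0, hi = (int)hx.size() - 1;
    // slope to hull vertices is unimodal in the vertex index
    while (hi - lo > 2) {
      int m1 = lo + (hi - lo) / 3, m2 = hi - (hi - lo) / 3;
      double s1 = (py - hy[m1]) / (px - hx[m1]);
      double s2 = (py - hy[m2]) / (px - hx[m2]);
      if (s1 < s2) lo = m1 + 1; else hi = m2;
    }
    double best = -1e300;
    for (int i = lo; i <= hi; ++i) {
      best = std::max(best, (py - hy[i]) / (px - hx[i]));
    }
    return best;
  }
};

// dl(k) for all k: max deviation of upper corners above the greatest
// convex minorant of the lower corners of points 0..k (excluding the
// deviation at k itself, whose upper corner is exempt at a mode atom).
std::vector<double> atom_violations(const std::vector<double>& x,
                                    const std::vector<double>& lc,
                                    const std::vector<double>& uc) {
  int m = (int)x.size();
  std::vector<double> out(m, 0.0);
  std::vector<int> hull;
  for (int k = 0; k < m; ++k) {
    // rebuild hull on 0..k (O(m^2) total; fine for the sizes used)
    hull.clear();
    for (int i = 0; i <= k; ++i) {
      while (hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        double cross = (x[b] - x[a]) * (lc[i] - lc[b]) -
                       (x[i] - x[b]) * (lc[b] - lc[a]);
        if (cross < 0) hull.pop_back(); else break;
      }
      hull.push_back(i);
    }
    double dev = 0.0;
    size_t seg = 0;
    for (int i = 0; i < k; ++i) {
      while (seg + 1 < hull.size() && hull[seg + 1] <= i) ++seg;
      double g;
      if (hull[seg] == i) g = lc[i];
      else {
        int a = hull[seg], b = hull[seg + 1];
        g = lc[a] + (lc[b] - lc[a]) * (x[i] - x[a]) / (x[b] - x[a]);
      }
      dev = std::max(dev, uc[i] - g);
    }
    out[k] = dev;
  }
  return out;
}

// fL_k(d) for all k on one side.
void junction_floor(const std::vector<double>& x,
                    const std::vector<double>& lc,
                    const std::vector<double>& uc,
                    double d, std::vector<double>& fL,
                    LiChao& tree) {
  int m = (int)x.size();
  fL.assign(m, 0.0);
  tree.init(&x);
  LowerHull hull;
  for (int k = 0; k < m; ++k) {
    double env = (k > 0) ? tree.query(k) : -1e300;
    fL[k] = std::max(lc[k] - d, env);
    double s = std::max(0.0, hull.max_slope(x[k], uc[k] - 2.0 * d));
    // line through (x[k], uc[k] - d) with slope s, valid for later k
    tree.add(s, (uc[k] - d) - s * x[k]);
    hull.add(x[k], lc[k]);
  }
}

} // namespace

// [[Rcpp::export]]
double dip_stat_cpp(Rcpp::NumericVector xs) {
  int n = xs.size();
  if (n < 2) return 0.0;
  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());

  std::vector<double> u, cnt;
  for (int i = 0; i < n; ++i) {
    if (!u.empty() && x[i] == u.back()) cnt.back() += 1.0;
    else { u.push_back(x[i]); cnt.push_back(1.0); }
  }
  int m = (int)u.size();
  if (m == 1) return 0.0;
  std::vector<double> lc(m), uc(m);
  double c = 0.0;
  for (int j = 0; j < m; ++j) {
    lc[j] = c / n;
    c += cnt[j];
    uc[j] = c / n;
  }
  // reflected data for the concave (right) side
  std::vector<double> xr(m), lcr(m), ucr(m);
  for (int j = 0; j < m; ++j) {
    xr[j] = -u[m - 1 - j];
    lcr[j] = 1.0 - uc[m - 1 - j];
    ucr[j] = 1.0 - lc[m - 1 - j];
  }
  std::vector<double> dl = atom_violations(u, lc, uc);
  std::vector<double> du_r = atom_violations(xr, lcr, ucr);
  std::vector<double> du(m);
  for (int j = 0; j < m; ++j) du[j] = du_r[m - 1 - j];

  LiChao treeL, treeR;
  std::vector<double> fL, fR;
  auto feasible = [&](double d) -> bool {
    junction_floor(u, lc, uc, d, fL, treeL);
    junction_floor(xr, lcr, ucr, d, fR, treeR);
    for (int k = 0; k < m; ++k) {
      if (dl[k] > 2.0 * d || du[k] > 2.0 * d) continue;
      double gR = 1.0 - fR[m - 1 - k];
      if (fL[k] <= gR + 1e-14) return true;
    }
    return false;
  };

  double lo = 0.0, hi = 0.25;
  if (feasible(lo)) return 0.0;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(mid)) hi = mid; else lo = mid;
  }
  return hi;
}
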