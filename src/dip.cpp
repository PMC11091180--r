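// Hartigan dip statistic, computed exactly from its definition:
// dip(F_n) = min over unimodal (convex-then-concave) CDFs G of sup|F_n - G|.
//
// For a candidate half-band width d, a unimodal G within the band exists iff
// for some mode index k there are values satisfying
//   * a nondecreasing convex function through the upper band at u_1..u_{k-1}
//     ending at v- <= hi_k that stays above the lower band, and
//   * a nondecreasing concave function starting at v+ in
//     [max(lo_k, v-), c_k/n + d] through the lower band at u_{k+1}..u_m that
//     stays below the upper band
// (the CDF may jump at the mode, v- < v+, which is why the two terminal
// values are separate). Feasibility of the convex part is checked via the
// lower convex hull of the upper band (the greatest convex minorant), and of
// the concave part via the upper concave hull of the lower band. The dip is
// then found by bisection on d; inner bisections find the minimal feasible
// terminal value v-.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// lower convex hull of (x, y), evaluated back at every x; x strictly increasing
void lower_hull_values(const std::vector<double>& x,
                       const std::vector<double>& y,
                       std::vector<double>& out) {
  const int n = (int)x.size();
  static thread_local std::vector<int> h;
  h.clear();
  for (int i = 0; i < n; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      // keep b only if it lies strictly below chord a-i
      double cross = (x[b] - x[a]) * (y[i] - y[a]) -
                     (y[b] - y[a]) * (x[i] - x[a]);
      if (cross <= 0.0) h.pop_back(); else break;
    }
    h.push_back(i);
  }
  out.assign(n, 0.0);
  size_t seg = 0;
  for (int i = 0; i < n; ++i) {
    while (seg + 1 < h.size() && x[h[seg + 1]] < x[i]) ++seg;
    if (seg + 1 >= h.size()) { out[i] = y[h[seg]]; continue; }
    int a = h[seg], b = h[seg + 1];
    if (x[i] <= x[a]) { out[i] = y[a]; continue; }
    double t = (x[i] - x[a]) / (x[b] - x[a]);
    out[i] = y[a] + t * (y[b] - y[a]);
  }
}

struct DipProblem {
  std::vector<double> u;   // unique sorted values
  std::vector<double> cum; // cumulative fractions c_i/n
  int m;
  double eps = 1e-12;

  double hi(int i, double d) const { // upper band at u_i (left limit)
    double v = (i == 0 ? 0.0 : cum[i - 1]) + d;
    return std::min(v, 1.0);
  }
  double lo(int i, double d) const { // lower band at u_i (right value)
    return std::max(cum[i] - d, 0.0);
  }

  // convex part over u_0..u_k with terminal value v at u_k (k 0-based)
  bool left_feasible(int k, double d, double v) const {
    if (k == 0) return v >= -eps;
    std::vector<double> xs(u.begin(), u.begin() + k + 1);
    std::vector<double> ys(k + 1);
    for (int i = 0; i < k; ++i) ys[i] = hi(i, d);
    ys[k] = v;
    static thread_local std::vector<double> hull;
    lower_hull_values(xs, ys, hull);
    for (int i = 0; i < k; ++i)
      if (hull[i] < lo(i, d) - 1e-10) return false;
    return true;
  }

  // concave part over u_k..u_{m-1} with fixed initial value v at u_k.
  // Reflect (x -> -x) and negate (y -> -y): a nondecreasing concave function
  // with fixed LEFT value v becomes a nondecreasing convex function with
  // fixed TERMINAL value -v, upper band -lo, lower band -hi, so the same
  // greatest-convex-minorant test applies.
  bool right_feasible(int k, double d, double v) const {
    if (k == m - 1) return v <= std::min(cum[k] + d, 1.0) + eps;
    int len = m - k;
    std::vector<double> xs(len), ys(len);
    for (int j = 0; j < len - 1; ++j) {
      int i = m - 1 - j; // original index, from the deep end toward k
      xs[j] = -u[i];
      ys[j] = -lo(i, d);
    }
    xs[len - 1] = -u[k];
    ys[len - 1] = -v;
    static thread_local std::vector<double> hull;
    lower_hull_values(xs, ys, hull);
    for (int j = 0; j < len - 1; ++j) {
      int i = m - 1 - j;
      if (hull[j] < -hi(i, d) - 1e-10) return false;
    }
    return true;
  }

  bool feasible(double d) const {
    for (int k = 0; k < m; ++k) {
      double hik = hi(k, d);
      if (!left_feasible(k, d, hik)) continue;
      // minimal feasible terminal value of the convex part
      double vlow = 0.0, vhigh = hik;
      if (left_feasible(k, d, vlow)) {
        vhigh = vlow;
      } else {
        for (int it = 0; it < 40; ++it) {
          double mid = 0.5 * (vlow + vhigh);
          if (left_feasible(k, d, mid)) vhigh = mid; else vlow = mid;
        }
      }
      double vminus = vhigh;
      double vplus = std::max(lo(k, d), vminus);
      if (vplus > std::min(cum[k] + d, 1.0) + eps) continue;
      if (right_feasible(k, d, vplus)) return true;
    }
    return false;
  }
};

} // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 observations");
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());

  DipProblem pb;
  int cnt = 0;
  for (int i = 0; i < n; ++i) {
    ++cnt;
    if (i == n - 1 || xs[i + 1] > xs[i]) {
      pb.u.push_back(xs[i]);
      pb.cum.push_back((double)cnt / n);
    }
  }
  pb.m = (int)pb.u.size();
  if (pb.m == 1) stop("all values identical; dip undefined");

  double dlo = 0.5 / n - 1e-9, dhi = 0.2500001;
  if (pb.feasible(dlo)) return 0.5 / n;
  for (int it = 0; it < 45; ++it) {
    double mid = 0.5 * (dlo + dhi);
    if (pb.feasible(mid)) dhi = mid; else dlo = mid;
  }
  return dhi;
}
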