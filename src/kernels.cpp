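#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Cross-matrix Manhattan distance: rows of A (m x g) vs rows of B (n x g).
// [[Rcpp::export(name = ".manhattan_cross")]]
NumericMatrix manhattan_cross(NumericMatrix A, NumericMatrix B) {
  const int m = A.nrow(), n = B.nrow(), g = A.ncol();
  NumericMatrix D(m, n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int l = 0; l < g; ++l) s += std::abs(A(i, l) - B(j, l));
      D(i, j) = s;
    }
  }
  return D;
}

// Cross-matrix Canberra distance; terms with both coordinates zero
// contribute 0 (standard convention).
// [[Rcpp::export(name = ".canberra_cross")]]
NumericMatrix canberra_cross(NumericMatrix A, NumericMatrix B) {
  const int m = A.nrow(), n = B.nrow(), g = A.ncol();
  NumericMatrix D(m, n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int l = 0; l < g; ++l) {
        double den = std::abs(A(i, l)) + std::abs(B(j, l));
        if (den > 0.0) s += std::abs(A(i, l) - B(j, l)) / den;
      }
      D(i, j) = s;
    }
  }
  return D;
}

// Weighted rank correlation between rows of RA (m x g) and RB (n x g), both
// already average-rank transformed (ascending: g = most expressed gene).
// Per-observation weights w_l = ra_l + rb_l make strongly expressed genes
// dominate the correlation; the statistic is the weighted Pearson
// correlation of the two rank vectors under those weights.
// [[Rcpp::export(name = ".weighted_rank_cross")]]
NumericMatrix weighted_rank_cross(NumericMatrix RA, NumericMatrix RB) {
  const int m = RA.nrow(), n = RB.nrow(), g = RA.ncol();
  NumericMatrix S(m, n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      double sw = 0, swx = 0, swy = 0;
      for (int l = 0; l < g; ++l) {
        double w = RA(i, l) + RB(j, l);
        sw += w;
        swx += w * RA(i, l);
        swy += w * RB(j, l);
      }
      double mx = swx / sw, my = swy / sw;
      double sxy = 0, sxx = 0, syy = 0;
      for (int l = 0; l < g; ++l) {
        double w = RA(i, l) + RB(j, l);
        double dx = RA(i, l) - mx, dy = RB(j, l) - my;
        sxy += w * dx * dy;
        sxx += w * dx * dx;
        syy += w * dy * dy;
      }
      double den = std::sqrt(sxx * syy);
      S(i, j) = (den > 0.0) ? sxy / den : 0.0;
    }
  }
  return S;
}

// ---------------------------------------------------------------------------
// Hartigan's dip statistic.
//
// Works in "midpoint count" units: the empirical cdf at the i-th order
// statistic is represented by c_i = i - 1/2, so that sup|F - G| <= t for a
// continuous cdf G is equivalent to |n G(x_i) - c_i| <= n t - 1/2 at every
// order statistic. A cdf in the closure of the unimodal class (convex, then
// a linear modal stretch, then concave) exists within deviation bands of
// half-width E/2 where E is computed below, giving dip = (1 + E) / (2 n).
//
// Hartigan's narrowing scheme: on the current interval, build the greatest
// convex minorant (lower hull) and least concave majorant (upper hull) of
// the midpoint ecdf points, find the largest vertical gap d between the two
// hulls (the cost of threading the modal line through the interval), and
// while d exceeds the deviations already incurred, narrow the modal interval
// to the gap location, charging the convexification / concavification
// deviations of the excluded flanks.
// ---------------------------------------------------------------------------

// first hull segment index k >= 1 with x[hull[k]] >= xq
static size_t find_seg(const std::vector<int>& hull, const NumericVector& x,
                       double xq) {
  size_t k = 1;
  while (k < hull.size() - 1 && x[hull[k]] < xq) ++k;
  return k;
}

static double hull_at(const std::vector<int>& hull, const NumericVector& x,
                      const NumericVector& c, double xq) {
  if (hull.size() == 1) return c[hull[0]];
  size_t k = find_seg(hull, x, xq);
  int a = hull[k - 1], b = hull[k];
  if (x[b] <= x[a]) return 0.5 * (c[a] + c[b]);
  double t = (xq - x[a]) / (x[b] - x[a]);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  return c[a] + t * (c[b] - c[a]);
}

// [[Rcpp::export(name = ".dip_stat")]]
double dip_stat(NumericVector xs) {
  const int n = xs.size();
  if (n < 2) return 0.0;
  NumericVector x = clone(xs).sort();
  if (x[n - 1] == x[0]) return 0.0;
  NumericVector c(n);
  for (int i = 0; i < n; ++i) c[i] = i + 0.5;

  int lo = 0, hi = n - 1;
  double E = 0.0;
  const double tol = 1e-12;

  for (int iter = 0; iter < 2 * n + 5; ++iter) {
    if (lo >= hi) break;
    if (x[lo] == x[hi]) { // pure tie block: threading is a vertical jump
      E = std::max(E, c[hi] - c[lo]);
      break;
    }
    // greatest convex minorant touch points on [lo, hi]
    std::vector<int> gcm;
    for (int i = lo; i <= hi; ++i) {
      if (!gcm.empty() && x[i] == x[gcm.back()]) continue; // keep lowest at tie
      while (gcm.size() >= 2) {
        int p1 = gcm[gcm.size() - 2], p2 = gcm.back();
        if ((c[p2] - c[p1]) * (x[i] - x[p2]) >= (c[i] - c[p2]) * (x[p2] - x[p1]))
          gcm.pop_back();
        else break;
      }
      gcm.push_back(i);
    }
    // least concave majorant touch points on [lo, hi]
    std::vector<int> lcm;
    for (int i = lo; i <= hi; ++i) {
      if (!lcm.empty() && x[i] == x[lcm.back()]) lcm.pop_back(); // keep highest
      while (lcm.size() >= 2) {
        int p1 = lcm[lcm.size() - 2], p2 = lcm.back();
        if ((c[p2] - c[p1]) * (x[i] - x[p2]) <= (c[i] - c[p2]) * (x[p2] - x[p1]))
          lcm.pop_back();
        else break;
      }
      lcm.push_back(i);
    }

    // largest vertical gap between the hulls, attained at a touch point
    double d = -1.0;
    int ig = lo, ih = hi;
    for (size_t t = 0; t < gcm.size(); ++t) {
      int i = gcm[t];
      double gap = hull_at(lcm, x, c, x[i]) - c[i];
      if (gap > d) {
        d = gap;
        ig = i;
        int ihc = (lcm.size() == 1) ? lcm[0] : lcm[find_seg(lcm, x, x[i])];
        ih = (ihc >= i) ? ihc : i;
      }
    }
    for (size_t t = 0; t < lcm.size(); ++t) {
      int j = lcm[t];
      double gap = c[j] - hull_at(gcm, x, c, x[j]);
      if (gap > d) {
        d = gap;
        ih = j;
        int igc = (gcm.size() == 1) ? gcm[0] : gcm[find_seg(gcm, x, x[j]) - 1];
        ig = (igc <= j) ? igc : j;
      }
    }

    if (d <= E + tol) break;

    // convexification deviation of the left flank [lo, ig] and
    // concavification deviation of the right flank [ih, hi]
    double e_l = 0.0;
    for (int i = lo; i <= ig; ++i) {
      double dev = c[i] - hull_at(gcm, x, c, x[i]);
      if (dev > e_l) e_l = dev;
    }
    double e_u = 0.0;
    for (int i = ih; i <= hi; ++i) {
      double dev = hull_at(lcm, x, c, x[i]) - c[i];
      if (dev > e_u) e_u = dev;
    }
    double En = std::max(E, std::max(e_l, e_u));
    if (ig <= lo && ih >= hi) { // cannot narrow further
      E = std::max(En, d);
      break;
    }
    E = En;
    lo = ig;
    hi = ih;
  }
  return (1.0 + E) / (2.0 * n);
}
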