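#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximum-likelihood (k0,k1,k2) IBD-mode coefficients per pair of
// individuals under the no-inbreeding model. Per-locus mode-conditional
// genotype-pair probabilities are passed as 9 x L tables (row index
// 3*g_i + g_j). Writing a1 = P1/P0 - 1, a2 = P2/P0 - 1, the relative
// log-likelihood is sum log(1 + k1 a1 + k2 a2), concave on the triangle
// {k1 >= 0, k2 >= 0, k1 + k2 <= 1}; it is maximized by projected Newton
// with Armijo backtracking, which handles the common boundary optima
// (unrelated and parent-offspring pairs) at quadratic rate.

static inline void project_triangle(double& x, double& y) {
  if (x < 0.0) x = 0.0;
  if (y < 0.0) y = 0.0;
  if (x + y > 1.0) {
    double t = (x - y + 1.0) / 2.0;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    x = t;
    y = 1.0 - t;
  }
}

static inline double loglik_rel(const std::vector<double>& a1,
                                const std::vector<double>& a2,
                                double k1, double k2) {
  double ll = 0.0;
  const int L = a1.size();
  for (int l = 0; l < L; ++l) {
    double den = 1.0 + k1 * a1[l] + k2 * a2[l];
    ll += std::log(den > 1e-300 ? den : 1e-300);
  }
  return ll;
}

// [[Rcpp::export(name = ".em_relatedness_pairs")]]
NumericMatrix em_relatedness_pairs(IntegerMatrix G, IntegerMatrix pairs,
                                   NumericMatrix T0, NumericMatrix T1,
                                   NumericMatrix T2, double tol,
                                   int max_iter) {
  const int np = pairs.nrow();
  const int L = G.ncol();
  NumericMatrix out(np, 4);
  std::vector<double> a1(L), a2(L);
  for (int pr = 0; pr < np; ++pr) {
    const int i = pairs(pr, 0) - 1;
    const int j = pairs(pr, 1) - 1;
    double ll0 = 0.0;
    for (int l = 0; l < L; ++l) {
      const int code = 3 * G(i, l) + G(j, l);
      const double p0 = T0(code, l);
      a1[l] = T1(code, l) / p0 - 1.0;
      a2[l] = T2(code, l) / p0 - 1.0;
      ll0 += std::log(p0 > 1e-300 ? p0 : 1e-300);
    }
    double k1 = 0.05, k2 = 0.05;
    double ll = loglik_rel(a1, a2, k1, k2);
    for (int it = 0; it < max_iter; ++it) {
      double g1 = 0.0, g2 = 0.0, h11 = 0.0, h12 = 0.0, h22 = 0.0;
      for (int l = 0; l < L; ++l) {
        double den = 1.0 + k1 * a1[l] + k2 * a2[l];
        if (den < 1e-300) den = 1e-300;
        const double w1 = a1[l] / den;
        const double w2 = a2[l] / den;
        g1 += w1; g2 += w2;
        h11 += w1 * w1; h12 += w1 * w2; h22 += w2 * w2;
      }
      // active-set Newton: constraints at their bound with an outward
      // gradient are dropped from the system, otherwise the full 2x2
      // solve yields vanishing steps along the active face
      const double ridge = 1e-8 * (h11 + h22 + 1.0);
      h11 += ridge; h22 += ridge;
      const bool lo1 = (k1 <= 1e-12 && g1 < 0.0);   // k1 = 0 binding
      const bool lo2 = (k2 <= 1e-12 && g2 < 0.0);   // k2 = 0 binding
      const bool hi = (k1 + k2 >= 1.0 - 1e-12 && g1 + g2 > 0.0); // k0 = 0
      double d1 = 0.0, d2 = 0.0;
      if (hi) {
        // restricted to the k0 = 0 edge, direction (1, -1)
        const double ge = h11 + h22 > 0.0 ? g1 - g2 : 0.0;
        const bool blocked = (k2 <= 1e-12 && ge > 0.0) ||
          (k1 <= 1e-12 && ge < 0.0);
        if (!blocked) {
          const double he = h11 - 2.0 * h12 + h22 + ridge;
          const double t = ge / (he > 1e-300 ? he : 1e-300);
          d1 = t; d2 = -t;
        }
      } else if (!lo1 && !lo2) {
        const double det = h11 * h22 - h12 * h12;
        if (det > 1e-300) {
          d1 = (h22 * g1 - h12 * g2) / det;
          d2 = (h11 * g2 - h12 * g1) / det;
        } else {
          d1 = g1 / (h11 + 1.0);
          d2 = g2 / (h22 + 1.0);
        }
      } else if (!lo1) {
        d1 = g1 / h11;
      } else if (!lo2) {
        d2 = g2 / h22;
      }
      // d stays (0,0) when every feasible constraint is binding: the
      // gradient fallback below then confirms (approximate) optimality
      double step = 1.0, ll_new = ll, k1n = k1, k2n = k2;
      bool improved = false;
      for (int bt = 0; bt < 40; ++bt) {
        double x = k1 + step * d1, y = k2 + step * d2;
        project_triangle(x, y);
        const double cand = loglik_rel(a1, a2, x, y);
        // strict improvement only: a vanishing backtracked step must fall
        // through to the gradient direction, not end the search
        if (cand > ll) {
          k1n = x; k2n = y; ll_new = cand;
          improved = true;
          break;
        }
        step *= 0.5;
      }
      if (!improved) {
        // projected-gradient fallback for steps whose Newton direction
        // leaves the feasible triangle
        const double gn = std::sqrt(g1 * g1 + g2 * g2) + 1e-300;
        step = 1.0 / gn;
        for (int bt = 0; bt < 40; ++bt) {
          double x = k1 + step * g1, y = k2 + step * g2;
          project_triangle(x, y);
          const double cand = loglik_rel(a1, a2, x, y);
          if (cand > ll && (x != k1 || y != k2)) {
            k1n = x; k2n = y; ll_new = cand;
            improved = true;
            break;
          }
          step *= 0.5;
        }
      }
      if (!improved) break;
      const double moved = std::fabs(k1n - k1) + std::fabs(k2n - k2);
      const double delta = ll_new - ll;
      k1 = k1n; k2 = k2n; ll = ll_new;
      if (delta < tol && moved < 1e-10) break;
      if (delta < tol && it > 2) break;
    }
    out(pr, 0) = 1.0 - k1 - k2;
    out(pr, 1) = k1;
    out(pr, 2) = k2;
    out(pr, 3) = ll + ll0;
  }
  return out;
}
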