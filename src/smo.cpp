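// Sequential minimal optimization for the box-constrained SVM dual.
//
// Solves max_a sum_j a_j - 1/2 sum_jk a_j a_k y_j y_k K_jk subject to
// sum_j y_j a_j = 0 and 0 <= a_j <= C, on a precomputed kernel matrix.
// Platt's two-loop heuristic with a full error cache; entirely
// deterministic (no RNG), second choices resolved by |E1-E2| with
// index-order fallback.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Smo {
  const NumericMatrix& K;
  const NumericVector& y;
  double C, tol;
  int n;
  std::vector<double> alpha, E;
  double b;
  long steps;

  Smo(const NumericMatrix& K_, const NumericVector& y_, double C_, double tol_)
      : K(K_), y(y_), C(C_), tol(tol_), n(y_.size()),
        alpha(n, 0.0), E(n), b(0.0), steps(0) {
    for (int i = 0; i < n; ++i) E[i] = -y[i];  // f = 0 initially
  }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2];
    double E1 = E[i1], E2 = E[i2];
    double s = y1 * y2;
    double L, H;
    if (s < 0) { L = std::max(0.0, a2 - a1); H = std::min(C, C + a2 - a1); }
    else       { L = std::max(0.0, a2 + a1 - C); H = std::min(C, a2 + a1); }
    if (H - L < 1e-15) return false;
    double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    double eta = 2.0 * k12 - k11 - k22;
    double a2new;
    if (eta < 0) {
      a2new = a2 - y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // flat direction: evaluate the dual at both ends
      double c1 = y2 * (E1 - E2);
      double obj_l = c1 * L - 0.5 * eta * L * L;  // up to a constant
      double obj_h = c1 * H - 0.5 * eta * H * H;
      if (obj_l > obj_h + 1e-12) a2new = L;
      else if (obj_h > obj_l + 1e-12) a2new = H;
      else return false;
    }
    if (std::fabs(a2new - a2) < 1e-14 * (a2new + a2 + 1e-14)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }

    double b1 = b - E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12;
    double b2 = b - E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22;
    double bnew;
    if (a1new > 0 && a1new < C) bnew = b1;
    else if (a2new > 0 && a2new < C) bnew = b2;
    else bnew = 0.5 * (b1 + b2);

    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2), db = bnew - b;
    for (int i = 0; i < n; ++i)
      E[i] += d1 * K(i1, i) + d2 * K(i2, i) + db;
    alpha[i1] = a1new; alpha[i2] = a2new; b = bnew;
    ++steps;
    return true;
  }

  int examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0)) {
      // 1st heuristic: maximize |E1 - E2| over non-bound points
      int best = -1; double bestgap = -1.0;
      for (int i = 0; i < n; ++i) {
        if (alpha[i] > 0 && alpha[i] < C) {
          double gap = std::fabs(E[i] - E2);
          if (gap > bestgap) { bestgap = gap; best = i; }
        }
      }
      if (best >= 0 && take_step(best, i2)) return 1;
      for (int i = 0; i < n; ++i)
        if (alpha[i] > 0 && alpha[i] < C && take_step(i, i2)) return 1;
      for (int i = 0; i < n; ++i)
        if (take_step(i, i2)) return 1;
    }
    return 0;
  }
};

}  // namespace

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-6, double max_steps = 1e7) {
  int n = y.size();
  if (K.nrow() != n || K.ncol() != n)
    stop("kernel matrix does not match label length");
  Smo s(K, y, C, tol);
  int num_changed = 0;
  bool examine_all = true;
  bool converged = true;
  while (num_changed > 0 || examine_all) {
    num_changed = 0;
    if (examine_all) {
      for (int i = 0; i < n; ++i) num_changed += s.examine(i);
    } else {
      for (int i = 0; i < n; ++i)
        if (s.alpha[i] > 0 && s.alpha[i] < C) num_changed += s.examine(i);
    }
    if (examine_all) examine_all = false;
    else if (num_changed == 0) examine_all = true;
    if (s.steps > (long)max_steps) { converged = false; break; }
  }
  return List::create(_["alpha"] = NumericVector(s.alpha.begin(), s.alpha.end()),
                      _["b"] = s.b,
                      _["steps"] = (double)s.steps,
                      _["converged"] = converged);
}
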