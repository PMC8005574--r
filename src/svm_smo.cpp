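#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Sequential minimal optimisation for the C-SVM dual with a linear kernel:
//   min_a 0.5 a' Q a - e' a,  0 <= a_i <= C,  sum_i y_i a_i = 0,
//   Q_ij = y_i y_j x_i . x_j.
// Maximal-violating-pair working-set selection. The gradient G is updated
// incrementally from the weight-vector change of each pair update, so one
// iteration costs O(n * d) with tight loops over raw arrays (d is 4 or 8
// band-power features here).

// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix X, NumericVector y, double C,
                 double tol = 1e-4, int max_iter = 2000000) {
  const int n = X.nrow(), d = X.ncol();
  // row-major copy for cache-friendly per-sample dot products
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) Xr[(size_t)i * d + j] = X(i, j);
  std::vector<double> alpha(n, 0.0), w(d, 0.0), G(n, -1.0), xsq(n);
  const double* yv = REAL(y);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double* xi = &Xr[(size_t)i * d];
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    xsq[i] = s;
  }

  int iter = 0;
  bool converged = false;
  std::vector<double> dw(d);
  while (iter < max_iter) {
    // maximal violating pair over I_up / I_low
    int i_up = -1, i_low = -1;
    double g_max = -std::numeric_limits<double>::infinity();
    double g_min = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double yg = -yv[t] * G[t];
      const bool pos = yv[t] > 0;
      const double a = alpha[t];
      if (((pos && a < C) || (!pos && a > 0)) && yg > g_max) { g_max = yg; i_up = t; }
      if (((pos && a > 0) || (!pos && a < C)) && yg < g_min) { g_min = yg; i_low = t; }
    }
    if (i_up < 0 || i_low < 0 || g_max - g_min < tol) { converged = true; break; }

    const int i = i_up, j = i_low;
    const double* xi = &Xr[(size_t)i * d];
    const double* xj = &Xr[(size_t)j * d];
    double kij = 0.0;
    for (int c = 0; c < d; ++c) kij += xi[c] * xj[c];
    double a2 = xsq[i] + xsq[j] - 2.0 * kij;
    if (a2 <= 0.0) a2 = 1e-12;

    // two-variable subproblem along the constraint y_i da_i + y_j da_j = 0,
    // clipped to the feasible segment of the box (Platt's L/H bounds on a_i)
    const double delta = (-yv[i] * G[i] + yv[j] * G[j]) / a2;
    const double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (yv[i] * yv[j] < 0) {          // a_i - a_j constant
      const double gamma = ai_old - aj_old;
      L = std::max(0.0, gamma);
      H = std::min(C, C + gamma);
    } else {                          // a_i + a_j constant
      const double gamma = ai_old + aj_old;
      L = std::max(0.0, gamma - C);
      H = std::min(C, gamma);
    }
    double ai = ai_old + yv[i] * delta;
    if (ai < L) ai = L;
    if (ai > H) ai = H;
    const double zeta = yv[i] * ai_old + yv[j] * aj_old;
    const double aj = yv[j] * (zeta - yv[i] * ai);

    const double di = ai - ai_old, dj = aj - aj_old;
    if (std::fabs(di) < 1e-15 && std::fabs(dj) < 1e-15) { converged = true; break; }
    alpha[i] = ai; alpha[j] = aj;
    for (int c = 0; c < d; ++c) {
      dw[c] = yv[i] * di * xi[c] + yv[j] * dj * xj[c];
      w[c] += dw[c];
    }
    for (int t = 0; t < n; ++t) {
      const double* xt = &Xr[(size_t)t * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) s += xt[c] * dw[c];
      G[t] += yv[t] * s;
    }
    ++iter;
  }

  auto decision = [&](int t) {
    const double* xt = &Xr[(size_t)t * d];
    double s = 0.0;
    for (int c = 0; c < d; ++c) s += xt[c] * w[c];
    return s;
  };

  // bias from free support vectors; fall back to the KKT interval midpoint
  double b = 0.0; int n_free = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 * C && alpha[t] < C * (1.0 - 1e-8)) {
      b += yv[t] - decision(t);
      ++n_free;
    }
  }
  if (n_free > 0) {
    b /= n_free;
  } else {
    // KKT: a=0,y=+1 or a=C,y=-1 give lower bounds on b; the others upper
    double ub = std::numeric_limits<double>::infinity();
    double lb = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double m = yv[t] - decision(t);
      const bool at_zero = alpha[t] <= 1e-8 * C;
      if ((yv[t] > 0 && at_zero) || (yv[t] < 0 && !at_zero)) lb = std::max(lb, m);
      else ub = std::min(ub, m);
    }
    b = (std::isfinite(ub) && std::isfinite(lb)) ? 0.5 * (ub + lb)
        : (std::isfinite(ub) ? ub : (std::isfinite(lb) ? lb : 0.0));
  }

  double wnorm2 = 0.0;
  for (int c = 0; c < d; ++c) wnorm2 += w[c] * w[c];
  double hinge = 0.0;
  for (int t = 0; t < n; ++t) {
    const double m = 1.0 - yv[t] * (decision(t) + b);
    if (m > 0.0) hinge += m;
  }

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["bias"] = b,
    _["objective"] = 0.5 * wnorm2 + C * hinge,
    _["iterations"] = iter,
    _["converged"] = converged);
}
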