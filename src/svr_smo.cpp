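#include <Rcpp.h>
#include <cmath>
#include <vector>

// Sequential minimal optimization for epsilon-insensitive support
// vector regression on a precomputed kernel matrix.
//
// Dual (libsvm formulation), variables t = 0..2n-1 with alpha_t in
// [0, C] and signs z_t = +1 (t < n), -1 (t >= n):
//   min 1/2 sum z_t z_u a_t a_u K(i_t, i_u) + sum p_t a_t
//   s.t. sum z_t a_t = 0,  p_t = eps - y_i (t < n), eps + y_i (t >= n)
// Maximal-violating-pair working-set selection; beta_i = a_i - a_{i+n}.

// [[Rcpp::export(name = ".svr_smo_cpp")]]
Rcpp::List svr_smo_cpp(Rcpp::NumericMatrix K, Rcpp::NumericVector y,
                       double C, double eps,
                       double tol = 1e-6, int max_iter = 500000) {
  const int n = y.size();
  const int N = 2 * n;
  std::vector<double> a(N, 0.0), G(N), z(N), p(N);
  for (int t = 0; t < N; ++t) {
    int i = t % n;
    z[t] = (t < n) ? 1.0 : -1.0;
    p[t] = (t < n) ? (eps - y[i]) : (eps + y[i]);
    G[t] = p[t];
  }
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  // boundary tolerance: variables numerically at a bound are clamped and
  // not selectable, preventing stuck maximal-violating pairs
  const double tb = 1e-10 * (C > 1.0 ? C : 1.0);
  while (iter < max_iter) {
    // working-set selection: maximal violating pair
    int ti = -1, tj = -1;
    m_up = -1e300; m_low = 1e300;
    for (int t = 0; t < N; ++t) {
      bool in_up = (z[t] > 0) ? (a[t] < C - tb) : (a[t] > tb);
      bool in_low = (z[t] > 0) ? (a[t] > tb) : (a[t] < C - tb);
      double v = -z[t] * G[t];
      if (in_up && v > m_up) { m_up = v; ti = t; }
      if (in_low && v < m_low) { m_low = v; tj = t; }
    }
    if (ti < 0 || tj < 0 || m_up - m_low < tol) break;
    int i = ti % n, j = tj % n;
    double eta = K(i, i) + K(j, j) - 2.0 * z[ti] * z[tj] * K(i, j);
    if (eta <= 1e-12) eta = 1e-12;
    // step d: a_ti += z_ti * d, a_tj -= z_tj * d
    double d = (m_up - m_low) / eta;
    // box clipping
    double lo = -1e300, hi = 1e300;
    if (z[ti] > 0) { lo = std::max(lo, -a[ti]); hi = std::min(hi, C - a[ti]); }
    else           { lo = std::max(lo, a[ti] - C); hi = std::min(hi, a[ti]); }
    if (z[tj] > 0) { lo = std::max(lo, a[tj] - C); hi = std::min(hi, a[tj]); }
    else           { lo = std::max(lo, -a[tj]); hi = std::min(hi, C - a[tj]); }
    if (d < lo) d = lo;
    if (d > hi) d = hi;
    if (std::fabs(d) < 1e-16) break;
    a[ti] += z[ti] * d;
    a[tj] -= z[tj] * d;
    // snap to the box to keep the selectable sets exact
    if (a[ti] < tb) a[ti] = 0.0;
    if (a[ti] > C - tb) a[ti] = C;
    if (a[tj] < tb) a[tj] = 0.0;
    if (a[tj] > C - tb) a[tj] = C;
    for (int t = 0; t < N; ++t) {
      int it = t % n;
      G[t] += z[t] * d * (K(it, i) - K(it, j));
    }
    ++iter;
  }
  // bias: average of -z_t G_t over free variables; else midpoint
  double bsum = 0.0; int bcnt = 0;
  for (int t = 0; t < N; ++t) {
    if (a[t] > tb && a[t] < C - tb) { bsum += -z[t] * G[t]; ++bcnt; }
  }
  double b;
  if (bcnt > 0) b = bsum / bcnt;
  else b = 0.5 * (m_up + m_low);
  Rcpp::NumericVector beta(n);
  for (int i = 0; i < n; ++i) beta[i] = a[i] - a[i + n];
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = iter < max_iter);
}
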