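#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Right-hand side of the gene-circuit ODE for one time window:
//   dx_i/dt = beta_i * prod(Hill terms over incoming edges)
//             - delta_i * x_i
//             + sum over mobility rows with dest i of D * (x_src^n - x_dst^n)
// Activation: x^h / (K^h + x^h); repression: K^h / (K^h + x^h).
// States are clamped at zero inside the kinetics.
static void rhs(const double t, const std::vector<double>& x,
                std::vector<double>& dx,
                const NumericVector& beta, const NumericVector& delta,
                const IntegerVector& e_tgt, const IntegerVector& e_reg,
                const IntegerVector& e_sign, const NumericVector& e_K,
                const NumericVector& e_h,
                const IntegerVector& m_dst, const IntegerVector& m_src,
                const NumericVector& m_D, const NumericVector& m_n) {
  const int ns = x.size();
  std::vector<double> prod(ns, 1.0);
  const int ne = e_tgt.size();
  for (int e = 0; e < ne; ++e) {
    double xr = x[e_reg[e]];
    if (xr < 0.0) xr = 0.0;
    const double Kh = std::pow(e_K[e], e_h[e]);
    const double xh = std::pow(xr, e_h[e]);
    const double term = (e_sign[e] >= 0) ? xh / (Kh + xh) : Kh / (Kh + xh);
    prod[e_tgt[e]] *= term;
  }
  for (int i = 0; i < ns; ++i)
    dx[i] = beta[i] * prod[i] - delta[i] * x[i];
  const int nm = m_dst.size();
  for (int m = 0; m < nm; ++m) {
    double xs = x[m_src[m]]; if (xs < 0.0) xs = 0.0;
    double xd = x[m_dst[m]]; if (xd < 0.0) xd = 0.0;
    dx[m_dst[m]] += m_D[m] * (std::pow(xs, m_n[m]) - std::pow(xd, m_n[m]));
  }
}

// Adaptive Cash-Karp RK45 integration over one window, reporting the state
// at each requested output time (t0 <= times, nondecreasing). Output times
// are hit exactly by clamping the step size.
// [[Rcpp::export(name = ".ode_window_cpp")]]
NumericMatrix ode_window_cpp(NumericVector x0, double t0, NumericVector times,
                             NumericVector beta, NumericVector delta,
                             IntegerVector e_tgt, IntegerVector e_reg,
                             IntegerVector e_sign, NumericVector e_K,
                             NumericVector e_h,
                             IntegerVector m_dst, IntegerVector m_src,
                             NumericVector m_D, NumericVector m_n,
                             double rtol, double atol) {
  static const double
    a2 = 0.2, a3 = 0.3, a4 = 0.6, a5 = 1.0, a6 = 0.875,
    b21 = 0.2,
    b31 = 3.0/40.0,  b32 = 9.0/40.0,
    b41 = 0.3, b42 = -0.9, b43 = 1.2,
    b51 = -11.0/54.0, b52 = 2.5, b53 = -70.0/27.0, b54 = 35.0/27.0,
    b61 = 1631.0/55296.0, b62 = 175.0/512.0, b63 = 575.0/13824.0,
    b64 = 44275.0/110592.0, b65 = 253.0/4096.0,
    c1 = 37.0/378.0, c3 = 250.0/621.0, c4 = 125.0/594.0, c6 = 512.0/1771.0,
    dc1 = c1 - 2825.0/27648.0, dc3 = c3 - 18575.0/48384.0,
    dc4 = c4 - 13525.0/55296.0, dc5 = -277.0/14336.0, dc6 = c6 - 0.25;

  const int ns = x0.size();
  const int nt = times.size();
  NumericMatrix out(ns, nt);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns),
      xt(ns), xerr(ns), x5(ns);

  double t = t0;
  const double tend = times[nt - 1];
  double h = (tend > t0) ? (tend - t0) / 100.0 : 0.0;
  const double hmin = (tend - t0) * 1e-12 + 1e-14;
  int next_out = 0;
  // report any output times equal to t0
  while (next_out < nt && times[next_out] <= t0 + hmin) {
    for (int i = 0; i < ns; ++i) out(i, next_out) = x[i];
    ++next_out;
  }
  long iter = 0;
  while (next_out < nt) {
    if (++iter > 10000000L) stop("ODE integration failed: step count exceeded");
    double tstop = times[next_out];
    if (t + h > tstop) h = tstop - t;
    if (h < hmin) h = hmin;

    rhs(t, x, k1, beta, delta, e_tgt, e_reg, e_sign, e_K, e_h, m_dst, m_src, m_D, m_n);
    for (int i = 0; i < ns; ++i) xt[i] = x[i] + h * b21 * k1[i];
    rhs(t + a2 * h, xt, k2, beta, delta, e_tgt, e_reg, e_sign, e_K, e_h, m_dst, m_src, m_D, m_n);
    for (int i = 0; i < ns; ++i) xt[i] = x[i] + h * (b31 * k1[i] + b32 * k2[i]);
    rhs(t + a3 * h, xt, k3, beta, delta, e_tgt, e_reg, e_sign, e_K, e_h, m_dst, m_src, m_D, m_n);
    for (int i = 0; i < ns; ++i) xt[i] = x[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    rhs(t + a4 * h, xt, k4, beta, delta, e_tgt, e_reg, e_sign, e_K, e_h, m_dst, m_src, m_D, m_n);
    for (int i = 0; i < ns; ++i) xt[i] = x[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
    rhs(t + a5 * h, xt, k5, beta, delta, e_tgt, e_reg, e_sign, e_K, e_h, m_dst, m_src, m_D, m_n);
    for (int i = 0; i < ns; ++i) xt[i] = x[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] + b64 * k4[i] + b65 * k5[i]);
    rhs(t + a6 * h, xt, k6, beta, delta, e_tgt, e_reg, e_sign, e_K, e_h, m_dst, m_src, m_D, m_n);

    double errmax = 0.0;
    for (int i = 0; i < ns; ++i) {
      x5[i] = x[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      xerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] + dc5 * k5[i] + dc6 * k6[i]);
      const double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(x5[i]));
      const double e = std::fabs(xerr[i]) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0 || h <= hmin * 1.5) {
      t += h;
      for (int i = 0; i < ns; ++i) x[i] = (x5[i] < 0.0) ? 0.0 : x5[i];
      while (next_out < nt && times[next_out] <= t + hmin) {
        for (int i = 0; i < ns; ++i) out(i, next_out) = x[i];
        ++next_out;
      }
      double fac = (errmax > 0.0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
    }
    if (!std::isfinite(h) || !std::isfinite(errmax))
      stop("ODE integration failed: non-finite state or step");
  }
  return out;
}
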