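#include <Rcpp.h>
using namespace Rcpp;

// Convolution with the discretized Bateman kernel h[k] = (a^k - b^k)/peak,
// implemented as the exact 2-pole recursive filter
//   y[n] = (a+b) y[n-1] - a b y[n-2] + c d[n-1],  c = (a-b)/peak.
static void conv_bateman(const std::vector<double>& d, std::vector<double>& y,
                         double a, double b, double c) {
  const int n = (int)d.size();
  double y1 = 0.0, y2 = 0.0;
  const double p1 = a + b, p2 = -a * b;
  for (int i = 0; i < n; ++i) {
    double x = (i > 0) ? c * d[i - 1] : 0.0;
    double yi = p1 * y1 + p2 * y2 + x;
    y2 = y1; y1 = yi;
    y[i] = yi;
  }
}

// adjoint: time-reversed application of the same filter
static void conv_bateman_adj(const std::vector<double>& v, std::vector<double>& y,
                             double a, double b, double c) {
  const int n = (int)v.size();
  double y1 = 0.0, y2 = 0.0;
  const double p1 = a + b, p2 = -a * b;
  for (int i = n - 1; i >= 0; --i) {
    double x = (i < n - 1) ? c * v[i + 1] : 0.0;
    double yi = p1 * y1 + p2 * y2 + x;
    y2 = y1; y1 = yi;
    y[i] = yi;
  }
}

// Projected FISTA for min 0.5||r - K d||^2 + 0.5 ridge ||d||^2, d >= 0.
// [[Rcpp::export(name = ".nnls_bateman_cpp")]]
List nnls_bateman_cpp(NumericVector r, double a, double b, double peak,
                      double ridge, int max_iter, double tol,
                      NumericVector warm) {
  const int n = r.size();
  const double c = (a - b) / peak;
  const double hmax = c / ((1.0 - a) * (1.0 - b));
  const double lip = hmax * hmax + ridge;
  std::vector<double> d(n), z(n), tmp(n), g(n);
  for (int i = 0; i < n; ++i) d[i] = warm[i] > 0 ? warm[i] : 0.0;
  z = d;
  double tk = 1.0;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    conv_bateman(z, tmp, a, b, c);
    for (int i = 0; i < n; ++i) tmp[i] -= r[i];
    conv_bateman_adj(tmp, g, a, b, c);
    double t_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    double step = 0.0, dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double dn = z[i] - (g[i] + ridge * z[i]) / lip;
      if (dn < 0.0) dn = 0.0;
      double diff = dn - d[i];
      if (std::fabs(diff) > step) step = std::fabs(diff);
      z[i] = dn + ((tk - 1.0) / t_new) * diff;
      d[i] = dn;
      if (dn > dmax) dmax = dn;
    }
    tk = t_new;
    if (step <= tol * std::max(1.0, dmax)) { converged = true; break; }
  }
  NumericVector driver(n), phasic(n);
  std::copy(d.begin(), d.end(), driver.begin());
  conv_bateman(d, tmp, a, b, c);
  std::copy(tmp.begin(), tmp.end(), phasic.begin());
  return List::create(_["driver"] = driver, _["phasic"] = phasic,
                      _["converged"] = converged, _["iterations"] = it);
}
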