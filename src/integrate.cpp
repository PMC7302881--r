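// Adaptive Dormand-Prince 5(4) integration of the N-species competition
// model with density-dependent mortality.
//
// Mortality kind codes (keep in sync with R/mortality.R):
//   0 hyperbolic 1/(1+s n); 1 exponential exp(-s n); 2 linear max(0, 1-s n);
//   3 density-independent control 1/(1+s ref).
//
// Zero density is absorbing: the derivative of a coordinate at 0 is exactly
// 0, so species pruned to 0 by the caller stay at 0 bitwise through all
// Runge-Kutta stages.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double mort_mult(int kind, double s, double ref, double n) {
  switch (kind) {
  case 0: return 1.0 / (1.0 + s * n);
  case 1: return std::exp(-s * n);
  case 2: { double v = 1.0 - s * n; return v > 0.0 ? v : 0.0; }
  default: return 1.0 / (1.0 + s * ref);
  }
}

struct CommunitySystem {
  const NumericMatrix comp, ri;
  const NumericVector delta;
  const double d;
  const IntegerVector kind;
  const NumericVector s, ref;
  const int N;

  CommunitySystem(const NumericMatrix& comp_, const NumericMatrix& ri_,
                  const NumericVector& delta_, double d_,
                  const IntegerVector& kind_, const NumericVector& s_,
                  const NumericVector& ref_)
    : comp(comp_), ri(ri_), delta(delta_), d(d_), kind(kind_), s(s_),
      ref(ref_), N(comp_.nrow()) {}

  void rhs(const std::vector<double>& n, std::vector<double>& out) const {
    for (int i = 0; i < N; ++i) {
      double ni = n[i];
      if (ni <= 0.0) { out[i] = 0.0; continue; }
      double cn = 0.0, rn = 0.0;
      for (int j = 0; j < N; ++j) {
        double nj = n[j];
        if (nj > 0.0) {
          cn += comp(i, j) * nj;
          rn += ri(i, j) * nj;
        }
      }
      // rn >= ri(i,i) * ni = ni > 0, so the division is safe.
      double m = d + delta[i] * (1.0 - d);
      out[i] = ni * ni / rn - ni * (cn + m * mort_mult(kind[i], s[i], ref[i], ni));
    }
  }
};

// [[Rcpp::export]]
NumericVector rhs_community_cpp(NumericMatrix comp, NumericMatrix ri,
                                NumericVector delta, double d,
                                IntegerVector kind, NumericVector s,
                                NumericVector ref, NumericVector n) {
  CommunitySystem sys(comp, ri, delta, d, kind, s, ref);
  std::vector<double> y(n.begin(), n.end()), dy(sys.N);
  sys.rhs(y, dy);
  return NumericVector(dy.begin(), dy.end());
}

// Dormand-Prince coefficients.
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order embedded weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Integrate the community ODE over a time window of length t_len.
// Returns the end state, the derivative there, and diagnostics.
// [[Rcpp::export]]
List integrate_window_cpp(NumericMatrix comp, NumericMatrix ri,
                          NumericVector delta, double d, IntegerVector kind,
                          NumericVector s, NumericVector ref,
                          NumericVector y0, double t_len,
                          double rtol = 1e-10, double atol = 1e-12,
                          double max_steps = 5e6) {
  CommunitySystem sys(comp, ri, delta, d, kind, s, ref);
  const int N = sys.N;
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(N), k2(N), k3(N), k4(N), k5(N), k6(N), k7(N),
      ytmp(N), ynew(N);

  double t = 0.0;
  sys.rhs(y, k1);
  double h = 1e-4;  // conservative; the controller adapts within a few steps
  if (h > t_len) h = t_len;
  bool success = true;
  double steps = 0.0;

  while (t < t_len) {
    if (steps >= max_steps) { success = false; break; }
    if (t + h > t_len) h = t_len - t;

    for (int i = 0; i < N; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    sys.rhs(ytmp, k2);
    for (int i = 0; i < N; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sys.rhs(ytmp, k3);
    for (int i = 0; i < N; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sys.rhs(ytmp, k4);
    for (int i = 0; i < N; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    sys.rhs(ytmp, k5);
    for (int i = 0; i < N; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    sys.rhs(ytmp, k6);
    for (int i = 0; i < N; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    sys.rhs(ynew, k7);

    double err = 0.0;
    for (int i = 0; i < N; ++i) {
      double y5 = ynew[i];
      double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5));
      double r = (y5 - y4) / sc;
      err += r * r;
    }
    err = std::sqrt(err / N);
    steps += 1.0;

    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < N; ++i) {
        // tiny negative excursions of decaying species are numerical noise
        y[i] = ynew[i] > 0.0 ? ynew[i] : 0.0;
        k1[i] = k7[i];  // FSAL
      }
      if (std::isnan(err)) { success = false; break; }
    }
    double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (!(h > 0.0) || std::isnan(h) || h < 1e-14 * std::max(1.0, t)) {
      success = false; break;
    }
  }

  sys.rhs(y, k1);
  double max_rhs = 0.0;
  for (int i = 0; i < N; ++i)
    max_rhs = std::max(max_rhs, std::fabs(k1[i]));

  return List::create(_["y"] = NumericVector(y.begin(), y.end()),
                      _["dy"] = NumericVector(k1.begin(), k1.end()),
                      _["t"] = t, _["steps"] = steps,
                      _["max_abs_rhs"] = max_rhs, _["success"] = success);
}
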