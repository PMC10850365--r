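#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// shortest angular difference a - b on a periodic 360-degree domain
static inline double wrap_diff(double a, double b) {
  double d = a - b;
  return d - 360.0 * std::floor((d + 180.0) / 360.0);
}

// Two-Gaussian-well periodic axis potential:
//   V(x) = d1 - d1 g(x - c1) - d2 g(x - c2),  g(u) = exp(-u^2 / (2 w^2))
// so V = 0 at the global well c1, offset d1 - d2 at c2, plateau d1.
static inline double axis_V(double x, double c1, double c2,
                            double d1, double d2, double w) {
  double u1 = wrap_diff(x, c1), u2 = wrap_diff(x, c2);
  return d1 - d1 * std::exp(-u1 * u1 / (2 * w * w))
            - d2 * std::exp(-u2 * u2 / (2 * w * w));
}

static inline double axis_dV(double x, double c1, double c2,
                             double d1, double d2, double w) {
  double u1 = wrap_diff(x, c1), u2 = wrap_diff(x, c2);
  return d1 * u1 / (w * w) * std::exp(-u1 * u1 / (2 * w * w))
       + d2 * u2 / (w * w) * std::exp(-u2 * u2 / (2 * w * w));
}

// [[Rcpp::export]]
NumericVector axis_potential_cpp(NumericVector x, double c1, double c2,
                                 double d1, double d2, double w) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = axis_V(x[i], c1, c2, d1, d2, w);
  return out;
}

// Overdamped Langevin (Euler-Maruyama) on the separable 2D potential.
// gamma dtheta = -V'(theta) dt + sqrt(2 gamma kbt) dW, angles in degrees.
// ax / ay hold (c1, c2, d1, d2, w) for the psi / phi axis.
// Records every `stride`-th step (the starting point is sample 0).
// [[Rcpp::export]]
NumericMatrix langevin2d_cpp(int n_steps, int stride, double dt,
                             double kbt, double friction,
                             NumericVector ax, NumericVector ay,
                             NumericVector start) {
  RNGScope scope;  // draws from R's RNG, so set.seed() governs the run
  int n_out = n_steps / stride + 1;
  NumericMatrix out(n_out, 2);
  double x = start[0], y = start[1];
  double drift = dt / friction;
  double noise = std::sqrt(2.0 * kbt * dt / friction);
  out(0, 0) = x; out(0, 1) = y;
  int row = 1;
  for (int i = 1; i <= n_steps; ++i) {
    x += -drift * axis_dV(x, ax[0], ax[1], ax[2], ax[3], ax[4])
         + noise * norm_rand();
    y += -drift * axis_dV(y, ay[0], ay[1], ay[2], ay[3], ay[4])
         + noise * norm_rand();
    // wrap into (-180, 180]
    x = x - 360.0 * std::floor((x + 180.0) / 360.0);
    y = y - 360.0 * std::floor((y + 180.0) / 360.0);
    if (i % stride == 0 && row < n_out) {
      out(row, 0) = x;
      out(row, 1) = y;
      ++row;
    }
  }
  return out;
}
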