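// Polya-Gamma PG(1, z) sampler via the Devroye-type alternating-series
// accept-reject scheme.  A PG(1, z) variate equals J*(1, z/2) / 4 where
// J* is the exponentially tilted Jacobi random variable; the proposal
// mixes a truncated inverse-Gaussian body with an exponential tail,
// split at t = 0.64.  Uses R's RNG so draws are governed by set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;
static const double MATH_PI = 3.141592653589793238462643383280;

// coefficients a_n(x) of the alternating series for the Jacobi density
static inline double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x <= TRUNC) {
    return MATH_PI * nph * std::pow(2.0 / (MATH_PI * x), 1.5) *
           std::exp(-2.0 * nph * nph / x);
  }
  return MATH_PI * nph * std::exp(-0.5 * nph * nph * MATH_PI * MATH_PI * x);
}

// CDF of inverse-Gaussian(mu = 1/z, lambda = 1) at x; valid for z >= 0
static inline double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  return R::pnorm(rx * (x * z - 1.0), 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-rx * (x * z + 1.0), 0.0, 1.0, 1, 0);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC]
static double rtigauss(double z) {
  double x;
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  if (mu > TRUNC) {
    // small z: propose from the z = 0 (Levy-type) law, thin by exp tilt
    while (true) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) break;
    }
  } else {
    // moderate/large z: draw IG(mu, 1) by the transform method, retry
    // until the draw lands inside the truncation interval
    do {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * (muy - std::sqrt(4.0 * muy + muy * muy));
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    } while (x > TRUNC);
  }
  return x;
}

// one draw from PG(1, z)
static double rpg1(double z) {
  z = 0.5 * std::fabs(z);
  double k = MATH_PI * MATH_PI / 8.0 + 0.5 * z * z;
  // proposal mixture masses: exponential tail on (t, inf), IG body on (0, t]
  double p = (MATH_PI / (2.0 * k)) * std::exp(-k * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  double x;
  while (true) {
    if (R::unif_rand() < p / (p + q)) {
      x = TRUNC + R::exp_rand() / k;
    } else {
      x = rtigauss(z);
    }
    // squeeze acceptance on the alternating series
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    bool accept = false, reject = false;
    while (!accept && !reject) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) accept = true;
      } else {
        s += a_coef(n, x);
        if (y > s) reject = true;
      }
    }
    if (accept) break;
  }
  return 0.25 * x;
}

//' Draw Polya-Gamma PG(1, z) variates
//'
//' @param z numeric vector of tilting parameters (one draw per element).
//' @return numeric vector of PG(1, z[i]) draws.
//' @keywords internal
// [[Rcpp::export(rpg_vec)]]
NumericVector rpg_vec(NumericVector z) {
  R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}
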