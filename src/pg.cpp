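#include <Rcpp.h>
using namespace Rcpp;

// Sampler for the Polya-Gamma distribution PG(1, z), used for data
// augmentation of the two logistic submodels. Exact alternating-series
// rejection sampler (Devroye-type) on the tilted Jacobi density J*(1, z/2),
// with PG(1, z) = J*(1, z/2) / 4. All randomness flows through R's RNG so
// that set.seed() gives bit-identical chains.

#define PG_TRUNC 0.64

// n-th coefficient of the alternating series for the J*(1,0) density.
static double a_coef(int n, double x) {
  double d = n + 0.5;
  if (x > PG_TRUNC)
    return M_PI * d * std::exp(-d * d * M_PI * M_PI * x / 2.0);
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * d * std::exp(-2.0 * d * d / x);
}

// CDF at x of the inverse-Gaussian(mu = 1/z, lambda = 1); handles z = 0.
static double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double t1 = R::pnorm(rx * (x * z - 1.0), 0.0, 1.0, 1, 0);
  // exp(2z) * Phi(-(xz+1)/sqrt(x)) computed on the log scale to avoid overflow
  double t2 = std::exp(2.0 * z + R::pnorm(-rx * (x * z + 1.0), 0.0, 1.0, 1, 1));
  return t1 + t2;
}

// Inverse-Gaussian(1/z, 1) truncated to (0, t).
static double rtigauss(double z, double t) {
  double x = t + 1.0;
  if (z < 1.0 / t) {
    // mean above the truncation point: rejection from the z = 0 proposal
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = R::norm_rand();
      y *= y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// One draw from PG(1, z).
double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double t = PG_TRUNC;
  double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * t);
  double q = 2.0 * std::exp(-z) * pigauss(t, z);
  for (;;) {
    double x;
    if (R::unif_rand() * (p + q) <= p)
      x = t + R::exp_rand() / K;      // exponential tail, x > t
    else
      x = rtigauss(z, t);             // truncated inverse-Gaussian, x < t
    // squeeze accept/reject on the alternating series
    double s = a_coef(0, x);
    double u = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (u <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (u > s) break;
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(int n, NumericVector z) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = rpg1(z[i % z.size()]);
  return out;
}
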