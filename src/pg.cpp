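// Polya-Gamma random variates by the Devroye-style alternating-series
// rejection sampler. PG(b, z) for integer b is drawn as a sum of b PG(1, z)
// variates, which suffices for per-offspring Bernoulli expansion of brood
// counts. Uses R's RNG so draws are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;

// piecewise coefficients a_n(x) of the alternating series for the
// Jacobi-type density on (0, Inf), split at the truncation point
static double a_coef(int n, double x) {
  double k = n + 0.5;
  if (x > TRUNC) {
    return M_PI * k * std::exp(-k * k * M_PI * M_PI * x / 2.0);
  } else {
    return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * k *
           std::exp(-2.0 * k * k / x);
  }
}

// CDF of inverse-Gaussian(mu, lambda = 1) at x; mu may be +Inf (Levy limit)
static double pigauss(double x, double mu) {
  if (x <= 0.0) return 0.0;
  double invsx = 1.0 / std::sqrt(x);
  double z1 = invsx * (x / mu - 1.0);
  double z2 = -invsx * (x / mu + 1.0);
  return R::pnorm(z1, 0.0, 1.0, 1, 0) +
         std::exp(2.0 / mu) * R::pnorm(z2, 0.0, 1.0, 1, 0);
}

// inverse-Gaussian(mu, 1) truncated to (0, TRUNC), z = 1/mu
static double rtigauss(double z) {
  double t = TRUNC;
  double mu = 1.0 / z;
  double X = t + 1.0;
  if (mu > t) {
    // rejection from truncated inverse-chi-square proposal
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double E1, E2;
      do {
        E1 = exp_rand();
        E2 = exp_rand();
      } while (E1 * E1 > 2.0 * E2 / t);
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = std::exp(-0.5 * z * z * X);
    }
  } else {
    // standard IG sampler, redraw until below the truncation point
    while (X > t) {
      double Y = norm_rand();
      Y *= Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * (muY - std::sqrt(4.0 * muY + muY * muY));
      if (unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// one PG(1, z) draw
static double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  // mixing weights of the exponential tail (x > t) and IG body (x < t)
  double p = (M_PI / (2.0 * fz)) * std::exp(-fz * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, mu);
  double ratio = p / (p + q);
  for (;;) {
    double X;
    if (unif_rand() < ratio) {
      X = TRUNC + exp_rand() / fz;
    } else {
      X = rtigauss(z);
    }
    // squeeze accept/reject via the alternating partial sums
    double S = a_coef(0, X);
    double Y = unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
  }
}

//' Polya-Gamma random draws
//'
//' Draws one PG(b[i], z[i]) variate per element, with integer shape b
//' sampled as a sum of PG(1, z) variates.
//'
//' @param b integer vector of shapes (>= 0; a zero shape yields 0).
//' @param z numeric vector of tilting parameters, recycled against b.
//' @return numeric vector of PG draws.
//' @export
// [[Rcpp::export]]
NumericVector rpg(IntegerVector b, NumericVector z) {
  R_xlen_t n = std::max(b.size(), z.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int bi = b[i % b.size()];
    double zi = z[i % z.size()];
    double s = 0.0;
    for (int j = 0; j < bi; ++j) s += rpg1(zi);
    out[i] = s;
  }
  return out;
}
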