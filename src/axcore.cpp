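#include <Rcpp.h>
using namespace Rcpp;

// Gyromagnetic ratio of 1H in rad / (ms * T); all lengths in micrometres,
// times in ms, diffusivities in um^2/ms throughout the compiled core.
static const double GAMMA_MS = 2.675e5;

// [[Rcpp::export]]
double gamma_ms() { return GAMMA_MS; }

// ln of the perpendicular echo attenuation for water restricted in an
// impermeable cylinder, Gaussian-phase-distribution expression for a
// rectangular-pulse PGSE/STEAM pair (finite delta), summed over the first
// length(roots) nonzero roots beta_m of J1'(beta)=0.
// Returns an n_radii x n_meas matrix.
// [[Rcpp::export]]
NumericMatrix cpp_gpd_lnatt(NumericVector radius, double d_intra,
                            NumericVector g_perp, NumericVector small_delta,
                            NumericVector big_delta, NumericVector roots) {
  const int nr = radius.size(), nm = g_perp.size(), nb = roots.size();
  NumericMatrix out(nr, nm);
  for (int i = 0; i < nr; ++i) {
    const double R = radius[i];
    if (R <= 0.0 || d_intra <= 0.0) {
      for (int j = 0; j < nm; ++j) out(i, j) = 0.0;
      continue;
    }
    for (int j = 0; j < nm; ++j) {
      const double g = g_perp[j];
      if (g == 0.0) { out(i, j) = 0.0; continue; }
      const double de = small_delta[j], De = big_delta[j];
      double s = 0.0;
      for (int m = 0; m < nb; ++m) {
        const double am2 = (roots[m] / R) * (roots[m] / R);
        const double dam2 = d_intra * am2;
        const double num = 2.0 * dam2 * de - 2.0
          + 2.0 * std::exp(-dam2 * de) + 2.0 * std::exp(-dam2 * De)
          - std::exp(-dam2 * (De - de)) - std::exp(-dam2 * (De + de));
        const double den = d_intra * d_intra * am2 * am2 * am2
          * (am2 * R * R - 1.0);
        s += num / den;
      }
      out(i, j) = -2.0 * GAMMA_MS * GAMMA_MS * g * g * s;
    }
  }
  return out;
}

// Analytic expectation of a Rician(nu, sigma) magnitude:
// sigma*sqrt(pi/2)*L_{1/2}(-nu^2/(2 sigma^2)), evaluated with
// exponentially scaled Bessel functions for numerical stability.
// [[Rcpp::export]]
NumericVector cpp_rician_mean(NumericVector nu, double sigma) {
  const int n = nu.size();
  NumericVector out(n);
  const double c = sigma * std::sqrt(M_PI / 2.0);
  for (int i = 0; i < n; ++i) {
    const double x = nu[i] * nu[i] / (2.0 * sigma * sigma);
    if (x > 5e4) { // asymptotic regime: E ~ sqrt(nu^2 + sigma^2) to O(1/x)
      out[i] = std::sqrt(nu[i] * nu[i] + sigma * sigma);
    } else {
      const double i0 = R::bessel_i(x / 2.0, 0.0, 2.0);
      const double i1 = R::bessel_i(x / 2.0, 1.0, 2.0);
      out[i] = c * ((1.0 + x) * i0 + x * i1);
    }
  }
  return out;
}

// Noise-free magnitude for a single-restricted-population voxel given a
// precomputed linear-scale perpendicular attenuation matrix `alin`
// (diameter grid x measurement) and Poisson count weights over that grid.
// Exposed for the fitting hot loop; the exported R compose function builds
// the same quantity through the module-level operations.
// [[Rcpp::export]]
NumericVector cpp_predict_single(NumericMatrix alin, NumericVector wts,
                                 NumericVector b, NumericVector cos2,
                                 NumericVector big_delta, NumericVector tm,
                                 bool steam, double delta_min, double d_a,
                                 double d_extra_ax,
                                 double f, double slope, double dperp_min,
                                 double s0, double t1) {
  const int nm = b.size(), nd = alin.nrow();
  NumericVector out(nm);
  for (int j = 0; j < nm; ++j) {
    double aperp = 0.0;
    for (int i = 0; i < nd; ++i) aperp += wts[i] * alin(i, j);
    const double restr = std::exp(-b[j] * cos2[j] * d_a) * aperp;
    double dp = dperp_min + slope * (big_delta[j] - delta_min);
    if (dp < 0.0) dp = 0.0;
    const double hind =
      std::exp(-b[j] * (dp + (d_extra_ax - dp) * cos2[j]));
    double sig = s0 * (f * restr + (1.0 - f) * hind);
    if (steam) sig *= std::exp(-tm[j] / t1);
    out[j] = sig;
  }
  return out;
}

// Monte-Carlo random-walk attenuation for 2-D diffusion inside a reflecting
// circle of radius R, rectangular gradient pulses perpendicular to the
// cylinder axis. Independent physics oracle for the GPD expression; uses
// R's RNG so set.seed() on the R side makes it reproducible.
// [[Rcpp::export]]
double cpp_mc_cylinder(double radius, double d_intra, double g_perp,
                       double small_delta, double big_delta,
                       int n_particles, double dt) {
  RNGScope scope;
  const double sd = std::sqrt(2.0 * d_intra * dt);
  const int n_steps = (int)std::ceil((big_delta + small_delta) / dt);
  double acc = 0.0;
  for (int p = 0; p < n_particles; ++p) {
    // uniform start in the disc
    double x, y;
    do {
      x = (2.0 * unif_rand() - 1.0) * radius;
      y = (2.0 * unif_rand() - 1.0) * radius;
    } while (x * x + y * y > radius * radius);
    double phase = 0.0;
    for (int s = 0; s < n_steps; ++s) {
      const double t = s * dt;
      x += sd * norm_rand();
      y += sd * norm_rand();
      double r2 = x * x + y * y;
      if (r2 > radius * radius) { // specular reflection about the wall
        const double r = std::sqrt(r2), k = (2.0 * radius - r) / r;
        x *= k; y *= k;
      }
      double gsign = 0.0;
      if (t < small_delta) gsign = 1.0;
      else if (t >= big_delta && t < big_delta + small_delta) gsign = -1.0;
      phase += gsign * GAMMA_MS * g_perp * x * dt;
    }
    acc += std::cos(phase);
  }
  return acc / n_particles;
}
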