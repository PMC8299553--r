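#include <Rcpp.h>
using namespace Rcpp;

// Polynomial evaluation sum_j c_j * x^(d_j); degree vectors are small.
static inline double polyval(const std::vector<int>& deg,
                             const std::vector<double>& coef, double x) {
  double out = 0.0;
  for (size_t j = 0; j < deg.size(); ++j) {
    double p = 1.0;
    for (int k = 0; k < deg[j]; ++k) p *= x;
    out += coef[j] * p;
  }
  return out;
}

static std::vector<int> as_ivec(IntegerVector v) {
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> as_dvec(NumericVector v) {
  return std::vector<double>(v.begin(), v.end());
}

// Euler-Maruyama for a scalar polynomial Langevin model, with optional
// structural polar Ito drift term sigma(x)^2/(2x). Draws one N(0,1) per
// step from R's RNG. Burn-in steps are integrated and discarded before the
// n_steps retained samples (the initial state is the first retained sample
// when burn_in = 0).
// [[Rcpp::export]]
NumericVector em_polynomial_cpp(int n_steps, int burn_in, double dt, double x0,
                                IntegerVector fdeg, NumericVector fcoef,
                                IntegerVector sdeg, NumericVector scoef,
                                bool polar) {
  std::vector<int> fd = as_ivec(fdeg), sd_ = as_ivec(sdeg);
  std::vector<double> fc = as_dvec(fcoef), sc = as_dvec(scoef);
  NumericVector out(n_steps);
  double x = x0;
  double sqdt = std::sqrt(dt);
  long total = (long)n_steps + burn_in;
  for (long k = 0; k < total; ++k) {
    if (k >= burn_in) out[k - burn_in] = x;
    double f = polyval(fd, fc, x);
    double s = polyval(sd_, sc, x);
    if (polar) f += s * s / (2.0 * x);
    x += f * dt + s * sqdt * norm_rand();
    if (!std::isfinite(x))
      stop("simulation blow-up: non-finite state at step %ld", k);
  }
  return out;
}

// Pitchfork normal form driven by an Ornstein-Uhlenbeck process:
//   dx = (lambda x - mu x^3 + eta) dt
//   deta = -alpha eta dt + sigma_eta dW.
// Integrated with 'substeps' internal Euler-Maruyama steps per retained
// sample so the fast OU scale alpha^-1 is resolved; one normal draw per
// internal step. Returns the x component only (eta is latent).
// [[Rcpp::export]]
NumericVector colored_pitchfork_cpp(int n_steps, int burn_in, double dt,
                                    int substeps,
                                    double x0, double eta0,
                                    double lambda, double mu,
                                    double alpha, double sigma_eta) {
  NumericVector out(n_steps);
  double x = x0, eta = eta0;
  double h = dt / substeps;
  double sqh = std::sqrt(h);
  long total = (long)n_steps + burn_in;
  for (long k = 0; k < total; ++k) {
    if (k >= burn_in) out[k - burn_in] = x;
    for (int m = 0; m < substeps; ++m) {
      double xn = x + (lambda * x - mu * x * x * x + eta) * h;
      eta += -alpha * eta * h + sigma_eta * sqh * norm_rand();
      x = xn;
    }
    if (!std::isfinite(x) || !std::isfinite(eta))
      stop("simulation blow-up: non-finite state at step %ld", k);
  }
  return out;
}

// Nondimensional double-well particle:
//   dx = v dt;  dv = ((eps - x^2) x - 2 v) dt + sigma dW.
// Returns the position x only.
// [[Rcpp::export]]
NumericVector double_well_cpp(int n_steps, int burn_in, double dt,
                              double x0, double v0,
                              double eps, double sigma) {
  NumericVector out(n_steps);
  double x = x0, v = v0;
  double sqdt = std::sqrt(dt);
  long total = (long)n_steps + burn_in;
  for (long k = 0; k < total; ++k) {
    if (k >= burn_in) out[k - burn_in] = x;
    double xn = x + v * dt;
    v += ((eps - x * x) * x - 2.0 * v) * dt + sigma * sqdt * norm_rand();
    x = xn;
    if (!std::isfinite(x) || !std::isfinite(v))
      stop("simulation blow-up: non-finite state at step %ld", k);
  }
  return out;
}

// Symmetric planar pitchfork with isotropic state-dependent noise:
//   dx = (lambda - mu r^2) x dt + sigma(r) dW_x
//   dy = (lambda - mu r^2) y dt + sigma(r) dW_y,   sigma(r) = s0 + s1 r^2.
// Returns r = sqrt(x^2 + y^2); the radial Ito drift term sigma^2/(2r)
// emerges exactly from this Cartesian realization. Two normal draws per
// step, x then y (fixed interleaving for reproducibility).
// [[Rcpp::export]]
NumericVector wake_surrogate_cpp(int n_steps, int burn_in, double dt,
                                 double x0, double y0,
                                 double lambda, double mu,
                                 double s0, double s1) {
  NumericVector out(n_steps);
  double x = x0, y = y0;
  double sqdt = std::sqrt(dt);
  long total = (long)n_steps + burn_in;
  for (long k = 0; k < total; ++k) {
    double r2 = x * x + y * y;
    if (k >= burn_in) out[k - burn_in] = std::sqrt(r2);
    double g = lambda - mu * r2;
    double s = s0 + s1 * r2;
    double zx = norm_rand();
    double zy = norm_rand();
    x += g * x * dt + s * sqdt * zx;
    y += g * y * dt + s * sqdt * zy;
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("simulation blow-up: non-finite state at step %ld", k);
  }
  return out;
}

// Hysteresis dwell-time detector: the phase switches to +1 on crossing
// 'upper' from below and to -1 on crossing 'lower' from above; returns the
// durations (in samples) between consecutive switches. The interval before
// the first switch is censored (its start is unobserved) and discarded.
// [[Rcpp::export]]
NumericVector dwell_times_cpp(NumericVector x, double upper, double lower) {
  std::vector<double> dur;
  int phase = 0;
  long last = -1;
  bool last_is_switch = false;
  for (long k = 0; k < x.size(); ++k) {
    int np = phase;
    if (x[k] >= upper) np = 1;
    else if (x[k] <= lower) np = -1;
    if (np != phase) {
      if (last_is_switch) dur.push_back((double)(k - last));
      last_is_switch = (phase != 0);
      phase = np;
      last = k;
    }
  }
  return wrap(dur);
}
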