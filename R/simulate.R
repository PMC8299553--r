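#' Simulation specification
#'
#' Settings shared by every generator: the retained sampling interval, the
#' number of retained samples, the initial state, the seed, the number of
#' burn-in samples integrated and discarded before recording (default 1% of
#' `n_steps`), and the number of internal integration substeps per retained
#' sample (the integrator step is `dt / substeps`; raise it when the system
#' contains scales faster than `dt`, e.g. a stiff noise process).
#'
#' @param dt Retained sampling interval (> 0).
#' @param n_steps Number of retained samples (>= 1).
#' @param initial_state Numeric vector; generators use the components they
#'   need (scalar systems use the first).
#' @param seed Integer seed; identical specs give bitwise-identical
#'   trajectories.
#' @param burn_in Discarded leading samples; default `ceiling(0.01 * n_steps)`.
#' @param substeps Internal Euler-Maruyama substeps per sample (default 1).
#' @return A list of class `"sim_spec"`.
#' @export
sim_spec <- function(dt = 0.01, n_steps = 1e5, initial_state = 0.5,
                     seed = 0L, burn_in = NULL, substeps = 1L) {
  if (dt <= 0) lr_error("'dt' must be positive", "invalid_argument")
  if (n_steps < 1) lr_error("'n_steps' must be >= 1", "invalid_argument")
  if (is.null(burn_in)) burn_in <- ceiling(0.01 * n_steps)
  if (substeps < 1) lr_error("'substeps' must be >= 1", "invalid_argument")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 initial_state = as.numeric(initial_state),
                 seed = as.integer(seed), burn_in = as.integer(burn_in),
                 substeps = as.integer(substeps)),
            class = "sim_spec")
}

#' Euler-Maruyama integration of a Langevin model
#'
#' Integrates `x_{k+1} = x_k + f(x_k) dt + sigma(x_k) sqrt(dt) z_k` with
#' i.i.d. standard normal `z_k` from the seeded generator (`substeps`
#' internal steps per retained sample). Library evaluation is used without
#' domain clamping, so trajectories may leave the declared model domain.
#'
#' @param model A `langevin_model` (polynomial libraries).
#' @param spec A `sim_spec`.
#' @return A `langevin_ts` of `n_steps` samples at interval `dt`.
#' @export
euler_maruyama <- function(model, spec = sim_spec()) {
  stopifnot(inherits(model, "langevin_model"), inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  h <- spec$dt / spec$substeps
  n_int <- spec$n_steps * spec$substeps
  x <- em_polynomial_cpp(
    n_int, spec$burn_in * spec$substeps, h, spec$initial_state[1],
    library_degrees(model$drift_library), model$drift_coeffs,
    library_degrees(model$diffusion_library), model$diffusion_coeffs,
    model$polar_ito_term
  )
  if (spec$substeps > 1L) x <- x[seq(1L, n_int, by = spec$substeps)]
  langevin_ts(x, spec$dt, "euler_maruyama")
}

#' Benchmark generator: pitchfork normal form with coloured forcing
#'
#' Co-integrates `dx = (lambda x - mu x^3 + eta) dt` with the
#' Ornstein-Uhlenbeck forcing `deta = -alpha eta dt + sigma_eta dW`
#' (relaxation time `alpha^-1`) and returns the `x` component only — the
#' forcing is latent. The defaults are the benchmark condition
#' `lambda = mu = 1`, `alpha = 100`, `sigma_eta = 50` (i.e.
#' `sigma_eta = 0.5 alpha`, so the effective white-noise amplitude seen by
#' the slow variable is `sigma_eta / alpha = 0.5`), which produces random
#' switching between the metastable states near +/- 1. The default 10
#' substeps resolve the OU scale (`alpha * dt / substeps = 0.1`).
#'
#' @param lambda,mu Drift coefficients (`mu > 0`).
#' @param alpha OU relaxation rate (> 0).
#' @param sigma_eta OU forcing amplitude.
#' @param spec A `sim_spec`; `initial_state = c(x0, eta0)` (a scalar is
#'   taken as `x0` with `eta0 = 0`).
#' @return A `langevin_ts` of the slow variable.
#' @export
simulate_colored_pitchfork <- function(lambda = 1, mu = 1, alpha = 100,
                                       sigma_eta = 50,
                                       spec = sim_spec(substeps = 10L)) {
  stopifnot(inherits(spec, "sim_spec"))
  if (mu <= 0) lr_error("'mu' must be positive", "invalid_argument")
  if (alpha <= 0) lr_error("'alpha' must be positive", "invalid_argument")
  set.seed(spec$seed)
  st <- spec$initial_state
  eta0 <- if (length(st) >= 2L) st[2] else 0
  x <- colored_pitchfork_cpp(spec$n_steps, spec$burn_in, spec$dt,
                             spec$substeps, st[1], eta0,
                             lambda, mu, alpha, sigma_eta)
  langevin_ts(x, spec$dt, "colored_pitchfork")
}

#' Benchmark generator: particle in a double-well potential
#'
#' The nondimensional second-order system `dx = v dt`,
#' `dv = ((eps - x^2) x - 2 v) dt + sigma dW` (fixed damping 2). The drift
#' undergoes a supercritical pitchfork bifurcation at `eps = 0`, with
#' stable equilibria at `x = +/- sqrt(eps)`. The default forcing follows
#' the rule `sigma = (eps + sqrt(eps)) / 2`, which keeps the mean dwell
#' time between wells of a similar order across `eps`. Returns the position
#' only: the velocity is a latent degree of freedom whose elimination makes
#' the recorded series non-Markovian at fine sampling — the order-reduction
#' benchmark.
#'
#' @param eps Bifurcation parameter.
#' @param sigma Forcing amplitude on the velocity; default
#'   `(eps + sqrt(eps)) / 2`.
#' @param spec A `sim_spec`; `initial_state = c(x0, v0)` (scalar: `v0 = 0`).
#' @return A `langevin_ts` of the position.
#' @export
simulate_double_well <- function(eps = 20,
                                 sigma = (eps + sqrt(eps)) / 2,
                                 spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  if (sigma < 0) lr_error("'sigma' must be non-negative", "invalid_argument")
  set.seed(spec$seed)
  st <- spec$initial_state
  v0 <- if (length(st) >= 2L) st[2] else 0
  h <- spec$dt / spec$substeps
  n_int <- spec$n_steps * spec$substeps
  x <- double_well_cpp(n_int, spec$burn_in * spec$substeps, h,
                       st[1], v0, eps, sigma)
  if (spec$substeps > 1L) x <- x[seq(1L, n_int, by = spec$substeps)]
  langevin_ts(x, spec$dt, "double_well")
}

#' Benchmark generator: radial wake surrogate
#'
#' Simulates the symmetric planar pitchfork
#' `dx = (lambda - mu r^2) x dt + sigma(r) dW_x` (and likewise for `y`)
#' with isotropic quadratic noise `sigma(r) = sigma0 + sigma1 r^2`, and
#' returns the radius `sqrt(x^2 + y^2)`. This Cartesian realization
#' produces exactly the radial Langevin equation
#' `dr = (lambda r - mu r^3 + sigma(r)^2/(2r)) dt + sigma(r) dW`, including
#' the structural Ito term, without ever integrating the singular radial
#' SDE. It is the stand-in generator for the turbulent-wake
#' centre-of-pressure benchmark, whose experimental data are not public.
#'
#' @param lambda,mu Drift coefficients (`mu > 0`).
#' @param sigma0,sigma1 Noise amplitude coefficients (`sigma(r) > 0`).
#' @param spec A `sim_spec`; `initial_state = c(x0, y0)` (scalar:
#'   `y0 = 0`).
#' @return A `langevin_ts` of the (non-negative) radius.
#' @export
simulate_wake_surrogate <- function(lambda = 1, mu = 1,
                                    sigma0 = 0.4, sigma1 = 0.2,
                                    spec = sim_spec(initial_state = c(1, 0))) {
  stopifnot(inherits(spec, "sim_spec"))
  if (mu <= 0) lr_error("'mu' must be positive", "invalid_argument")
  if (sigma0 <= 0 || sigma1 < 0) {
    lr_error("need sigma0 > 0 and sigma1 >= 0 so sigma(r) > 0", "invalid_argument")
  }
  set.seed(spec$seed)
  st <- spec$initial_state
  y0 <- if (length(st) >= 2L) st[2] else 0
  h <- spec$dt / spec$substeps
  n_int <- spec$n_steps * spec$substeps
  r <- wake_surrogate_cpp(n_int, spec$burn_in * spec$substeps, h,
                          st[1], y0, lambda, mu, sigma0, sigma1)
  if (spec$substeps > 1L) r <- r[seq(1L, n_int, by = spec$substeps)]
  langevin_ts(r, spec$dt, "wake_surrogate")
}

#' Metastable dwell times
#'
#' Hysteresis two-state detector: the phase switches to `+` when the series
#' crosses `upper` and to `-` when it crosses `lower`; the time between
#' consecutive switches is one dwell. The two thresholds suppress
#' within-well chatter. An empty result (no switching) is valid.
#'
#' @param ts A `langevin_ts` (or numeric vector with `dt` attribute 1).
#' @param upper,lower Switching thresholds (`upper > lower`); default
#'   `+/- half` the series' root-mean-square.
#' @return Numeric vector of dwell durations in time units.
#' @export
dwell_times <- function(ts, upper = NULL, lower = NULL) {
  x <- if (inherits(ts, "langevin_ts")) ts$values else as.numeric(ts)
  dt <- if (inherits(ts, "langevin_ts")) ts$dt else 1
  if (is.null(upper)) upper <- 0.5 * sqrt(mean(x^2))
  if (is.null(lower)) lower <- -upper
  if (upper <= lower) lr_error("'upper' must exceed 'lower'", "invalid_argument")
  dwell_times_cpp(x, upper, lower) * dt
}

#' Welch power spectral density
#'
#' Averaged-periodogram estimate with Hann tapering and 50% segment
#' overlap; one-sided density normalization (the integral over frequency
#' approximates the series variance).
#'
#' @param ts A `langevin_ts`.
#' @param segment_length Samples per segment (<= series length); default
#'   `2^floor(log2(n/8))`.
#' @return A data frame with columns `frequency` (cycles per time unit) and
#'   `power`.
#' @export
power_spectrum <- function(ts, segment_length = NULL) {
  stopifnot(inherits(ts, "langevin_ts"))
  x <- ts$values
  n <- length(x)
  if (is.null(segment_length)) segment_length <- max(8L, 2^floor(log2(n / 8)))
  segment_length <- as.integer(segment_length)
  if (segment_length > n) {
    lr_error("'segment_length' exceeds the series length", "invalid_argument")
  }
  fs <- 1 / ts$dt
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segment_length) / (segment_length + 1)))
  step <- max(1L, segment_length %/% 2L)
  starts <- seq(1L, n - segment_length + 1L, by = step)
  nf <- segment_length %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment_length - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * sum(w^2))
  }
  p <- acc / length(starts)
  # One-sided: double everything except DC (and Nyquist for even lengths).
  dbl <- rep(2, nf); dbl[1] <- 1
  if (segment_length %% 2L == 0L) dbl[nf] <- 1
  data.frame(
    frequency = (seq_len(nf) - 1L) * fs / segment_length,
    power = p * dbl
  )
}
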