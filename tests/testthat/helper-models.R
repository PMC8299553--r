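# Shared model fixtures, built in code.

# OU: f = -theta x, sigma = s (a = s^2/2), stationary N(0, s^2/(2 theta)).
ou_model <- function(theta = 1, s = sqrt(2), domain = c(-Inf, Inf)) {
  langevin_model(
    polynomial_library(1, "odd", "drift"), -theta,
    polynomial_library(0, "all", "diffusion"), s,
    domain = domain
  )
}

# Bistable cubic: f = lambda x - mu x^3, constant sigma.
cubic_model <- function(lambda = 1, mu = 1, s = 0.5, domain = c(-Inf, Inf)) {
  pitchfork_model(lambda, mu, s, domain = domain)
}

# Pure Brownian motion: f = 0, sigma = s.
brownian_model <- function(s = 1) {
  langevin_model(
    polynomial_library(1, "odd", "drift"), 0,
    polynomial_library(0, "all", "diffusion"), s
  )
}

# Exact OU transition sampling (AR(1)), independent of the Euler-Maruyama
# code path; used as a simulation-free oracle source.
ou_exact_series <- function(n, dt, theta = 1, s = sqrt(2), x0 = 0, seed = 1) {
  set.seed(seed)
  rho <- exp(-theta * dt)
  sd_step <- sqrt(s^2 / (2 * theta) * (1 - rho^2))
  x <- numeric(n)
  x[1] <- x0
  z <- rnorm(n - 1)
  for (k in 2:n) x[k] <- rho * x[k - 1] + sd_step * z[k - 1]
  langevin_ts(x, dt, "ou_exact")
}

# Closed-form OU finite-time conditional moments.
ou_m1_exact <- function(x, theta, tau) x * (exp(-theta * tau) - 1)
ou_m2_exact <- function(x, theta, s, tau) {
  x^2 * (exp(-theta * tau) - 1)^2 + s^2 / (2 * theta) * (1 - exp(-2 * theta * tau))
}

as_epdf <- function(grid, density) {
  structure(list(grid = grid, density = density), class = "empirical_pdf")
}
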