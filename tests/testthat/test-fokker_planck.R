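test_that("adjoint stencil reduces to the Laplacian for pure diffusion", {
  m <- brownian_model(sqrt(2))  # a = 1
  g <- grid1d(-1, 1, 21)
  ops <- build_operators(m, g)
  h <- g$h
  for (i in c(2, 10, 20)) {
    expect_equal(ops$adjoint[i, (i - 1):(i + 1)], c(1, -2, 1) / h^2)
  }
  # forward conserves probability: column sums vanish
  expect_lt(max(abs(colSums(ops$forward))), 1e-9 / h^2)
})

test_that("forward operator annihilates the OU stationary density at 2nd order", {
  m <- ou_model(1, sqrt(2))
  res_at <- function(n) {
    g <- grid1d(-6, 6, n)
    ops <- build_operators(m, g)
    p <- dnorm(g$centers)
    max(abs(ops$forward %*% p))[1]
  }
  r1 <- res_at(100); r2 <- res_at(200)
  expect_lt(r2, 1e-3)
  expect_gt(r1 / r2, 3)  # ~4x per halving of h
})

test_that("forward and adjoint are discretely dual on interior test fields", {
  # The conservative flux form is the exact discrete transpose of the
  # central-difference adjoint away from the boundary rows, so the duality
  # gap <L p, q> - <p, L+ q> sits at machine precision for compactly
  # supported fields, at every resolution.
  m <- cubic_model(1, 1, 0.7)
  dual_gap <- function(n) {
    g <- grid1d(-3, 3, n)
    ops <- build_operators(m, g)
    x <- g$centers
    p <- exp(-1 / pmax(1 - (x / 2.5)^2, 1e-12)) * (abs(x) < 2.5)
    q <- sin(x) * p
    abs(sum((ops$forward %*% p) * q) - sum(p * (ops$adjoint %*% q))) * g$h
  }
  expect_lt(dual_gap(100), 1e-12)
  expect_lt(dual_gap(200), 1e-12)
})

test_that("finite-time moments reproduce the OU closed form", {
  theta <- 1.3; s <- 1.1; tau <- 0.4
  m <- ou_model(theta, s)
  g <- grid1d(-4, 4, 200)
  ftm <- finite_time_moments(m, g, tau)
  x <- g$centers
  m1e <- ou_m1_exact(x, theta, tau)
  m2e <- ou_m2_exact(x, theta, s, tau)
  # linear drift keeps polynomials closed => near machine precision
  expect_equal(ftm$m1, m1e, tolerance = 1e-8)
  expect_equal(ftm$m2, m2e, tolerance = 1e-8)
})

test_that("Brownian moments: m1 = 0, m2 = s^2 tau away from boundaries", {
  s <- 0.9; tau <- 0.2
  m <- brownian_model(s)
  g <- grid1d(-2, 2, 80)
  ftm <- finite_time_moments(m, g, tau, extend = 0.5)
  i <- 20:60
  expect_lt(max(abs(ftm$m1[i])), 1e-8)
  expect_equal(ftm$m2[i], rep(s^2 * tau, length(i)), tolerance = 1e-6)
})

test_that("tau = 0 gives identically zero corrections", {
  m <- cubic_model()
  g <- grid1d(-2, 2, 50)
  ftm <- finite_time_moments(m, g, 0)
  expect_identical(ftm$m1, numeric(50))
  expect_identical(ftm$m2, numeric(50))
  expect_error(finite_time_moments(m, g, -0.1), class = "invalid_argument")
})

test_that("m1/tau -> f and m2/(2 tau) -> a as tau -> 0", {
  m <- cubic_model(1, 1, 0.6)
  g <- grid1d(-2, 2, 60)
  x <- g$centers
  f <- evaluate_drift(m, x); a <- evaluate_a(m, x)
  i <- 10:50
  errs <- vapply(c(0.1, 0.05, 0.025), function(tau) {
    ftm <- finite_time_moments(m, g, tau)
    max(abs(ftm$m1[i] / tau - f[i]), abs(ftm$m2[i] / (2 * tau) - a[i]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))                 # shrinks with tau
  expect_gt(errs[1] / errs[3], 2.5)                # ~first order in tau
  expect_lt(errs[3], 0.1)
})

test_that("stationary densities: analytic forms and numeric agreement", {
  g <- grid1d(-4, 4, 200)
  # OU with unit variance -> standard normal
  pa <- stationary_pdf_analytic(ou_model(1, sqrt(2)), g)
  expect_equal(pa$density, dnorm(g$centers), tolerance = 1e-4)
  expect_equal(sum(pa$density) * g$h, 1, tolerance = 1e-8)
  # bistable cubic: bimodal with maxima nearest x = +/- 1
  pb <- stationary_pdf_analytic(cubic_model(1, 1, 0.5), g)
  peaks <- g$centers[order(pb$density, decreasing = TRUE)[1:2]]
  expect_equal(sort(peaks), c(-1, 1), tolerance = g$h)
  # numeric null-vector solver matches analytic for both models
  for (m in list(ou_model(1, sqrt(2)), cubic_model(1, 1, 0.5))) {
    pn <- stationary_pdf_numeric(m, g)
    expect_equal(sum(pn$density) * g$h, 1, tolerance = 1e-8)
    expect_true(all(pn$density >= 0))
    pa <- stationary_pdf_analytic(m, g)
    expect_lt(kl_divergence(as_epdf(g, pa$density), pn), 1e-4)
  }
  # pure diffusion with zero-flux boundaries -> uniform density
  pu <- stationary_pdf_numeric(brownian_model(1), grid1d(-1, 1, 60))
  expect_equal(pu$density, rep(0.5, 60), tolerance = 1e-6)
})

test_that("probability is conserved under the forward semigroup", {
  m <- cubic_model(1, 1, 0.5)
  g <- grid1d(-3, 3, 80)
  ops <- build_operators(m, g)
  E <- as.matrix(Matrix::expm(Matrix::Matrix(0.5 * ops$forward)))
  p0 <- dnorm(g$centers, 0.5, 0.3); p0 <- p0 / (sum(p0) * g$h)
  p1 <- drop(E %*% p0)
  expect_equal(sum(p1) * g$h, 1, tolerance = 1e-8)
})

test_that("grid refinement shows second-order convergence of the moments", {
  # nonlinear drift so the discretization error is non-trivial
  m <- cubic_model(1, 1, 0.6)
  tau <- 0.2
  err_at <- function(n) {
    g <- grid1d(-2, 2, n)
    ftm <- finite_time_moments(m, g, tau, extend = 0.5)
    gref <- grid1d(-2, 2, 8 * n)
    fref <- finite_time_moments(m, gref, tau, extend = 0.5)
    # compare on shared centers (every 8th refined cell midpoint aligns)
    idx <- seq(5, 8 * n, by = 8) - 0  # refined centers nearest coarse ones
    approx_ref <- stats::approx(gref$centers, fref$m1, g$centers)$y
    max(abs(ftm$m1 - approx_ref), na.rm = TRUE)
  }
  e1 <- err_at(50); e2 <- err_at(100)
  expect_gt(e1 / e2, 3)  # ~4x per halving
})

test_that("infeasible diffusion is signalled when building operators", {
  bad <- langevin_model(
    polynomial_library(1, "odd", "drift"), 0,
    polynomial_library(2, "even", "diffusion"), c(1, -1)
  )
  expect_warning(build_operators(bad, grid1d(-2, 2, 30)),
                 class = "infeasible_model")
})
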