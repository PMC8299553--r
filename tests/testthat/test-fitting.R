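# Build a self-consistent binned_moments/empirical_pdf pair directly from a
# model's own finite-time moments (no sampling noise): the cost of the
# generating model must be exactly zero.
selfconsistent_data <- function(model, grid, tau) {
  ftm <- finite_time_moments(model, grid, tau)
  binned <- structure(
    list(grid = grid, tau = tau, m1 = ftm$m1, m2 = ftm$m2,
         counts = rep(100L, grid$n_bins),
         w1 = rep(1, grid$n_bins), w2 = rep(1, grid$n_bins),
         valid = rep(TRUE, grid$n_bins)),
    class = "binned_moments"
  )
  p <- stationary_pdf_analytic(model, grid)
  list(binned = binned, p_hat = as_epdf(grid, p$density))
}

test_that("moment cost is zero at the truth and rises under perturbation", {
  m <- cubic_model(1, 1, 0.5)
  g <- grid1d(-2, 2, 40)
  dat <- selfconsistent_data(m, g, 0.3)
  expect_equal(moment_cost(m, dat$binned), 0, tolerance = 1e-12)
  for (delta in c(0.05, -0.05, 0.2)) {
    m2 <- m; m2$drift_coeffs[1] <- m2$drift_coeffs[1] + delta
    expect_gt(moment_cost(m2, dat$binned), 1e-6)
  }
  # infeasible model gets the finite penalty, not an error
  bad <- m; bad$diffusion_coeffs <- -0.5
  expect_equal(moment_cost(bad, dat$binned), 1e10)
})

test_that("kl_divergence matches the closed-form Gaussian value", {
  g <- grid1d(-8, 8, 800)
  p1 <- dnorm(g$centers); p1 <- p1 / (sum(p1) * g$h)
  p2 <- dnorm(g$centers, 0.5, 1); p2 <- p2 / (sum(p2) * g$h)
  expect_equal(kl_divergence(as_epdf(g, p1), as_epdf(g, p1)), 0)
  # D_KL(N(0,1) || N(0.5,1)) = (0.5)^2 / 2 = 0.125
  expect_equal(kl_divergence(as_epdf(g, p1), as_epdf(g, p2)), 0.125,
               tolerance = 1e-3)
  expect_gte(kl_divergence(as_epdf(g, p2), as_epdf(g, p1)), 0)
  expect_error(
    kl_divergence(as_epdf(g, p1), as_epdf(grid1d(-1, 1, 10), rep(0.5, 10))),
    class = "invalid_argument"
  )
})

test_that("total_cost decomposes linearly in eta", {
  m <- cubic_model(1, 1, 0.5)
  g <- grid1d(-2, 2, 40)
  dat <- selfconsistent_data(m, g, 0.3)
  # off-truth model so both terms are nonzero
  m2 <- m; m2$drift_coeffs <- c(0.7, -0.8); m2$diffusion_coeffs <- 0.6
  c0 <- total_cost(m2, dat$binned, dat$p_hat, eta = 0)
  c1 <- total_cost(m2, dat$binned, dat$p_hat, eta = 1)
  c2 <- total_cost(m2, dat$binned, dat$p_hat, eta = 2)
  expect_equal(c0$total, c0$moment_term)
  expect_equal(c1$total, c1$moment_term + c1$kl_term)
  expect_equal(c2$total - c2$moment_term, 2 * (c1$total - c1$moment_term),
               tolerance = 1e-10)
  # self-consistent truth: exactly zero total
  ct <- total_cost(m, dat$binned, dat$p_hat, eta = 1)
  expect_lt(ct$total, 1e-10)
})

test_that("the automatic eta rule picks the nearest power of ten", {
  expect_equal(langreg:::nearest_pow10(0.8), 1)
  expect_equal(langreg:::nearest_pow10(3e-3), 1e-3)
  expect_equal(langreg:::nearest_pow10(0), 1e-6)
  expect_equal(langreg:::nearest_pow10(40), 100)  # log10(40) = 1.6 -> 10^2
})

test_that("fit recovers a cubic model from fast-sampled white-noise data", {
  ts <- euler_maruyama(cubic_model(1, 1, 0.5),
                       sim_spec(dt = 0.01, n_steps = 1e6, seed = 4,
                                initial_state = 1))
  cfg <- fit_config(stride = 5, seed = 4)
  res <- fit_langevin(pitchfork_model(0, 0, 0.1), ts, cfg)
  expect_true(res$converged)
  expect_equal(res$model$drift_coeffs[1], 1, tolerance = 0.1)
  expect_equal(res$model$drift_coeffs[2], -1, tolerance = 0.1)
  expect_equal(res$model$diffusion_coeffs[1], 0.5, tolerance = 0.05)
  # reported cost equals re-evaluation on the returned model
  re <- total_cost(res$model, res$binned, res$p_hat, eta = res$eta)
  expect_equal(res$cost$total, re$total, tolerance = 1e-9)
})

test_that("fit_no_adjoint handles limit cases", {
  # Brownian data with an odd drift library: coefficients ~ 0
  ts <- euler_maruyama(brownian_model(1),
                       sim_spec(dt = 0.01, n_steps = 2e5, seed = 6))
  cfg <- fit_config(stride = 1, seed = 6)
  res <- fit_no_adjoint(pitchfork_model(0, 0, 0.1), ts, cfg)
  expect_lt(max(abs(res$model$drift_coeffs)), 0.2)
  expect_equal(res$model$diffusion_coeffs[1], 1, tolerance = 0.05)
})

test_that("fit is deterministic given the seed", {
  ts <- euler_maruyama(cubic_model(1, 1, 0.5),
                       sim_spec(dt = 0.01, n_steps = 2e5, seed = 8,
                                initial_state = 1))
  cfg <- fit_config(stride = 5, seed = 123, maxit = 100)
  r1 <- fit_langevin(pitchfork_model(0, 0, 0.1), ts, cfg)
  r2 <- fit_langevin(pitchfork_model(0, 0, 0.1), ts, cfg)
  expect_identical(r1$model$drift_coeffs, r2$model$drift_coeffs)
  expect_identical(r1$model$diffusion_coeffs, r2$model$diffusion_coeffs)
})

test_that("ssr removes spurious terms and keeps the true active set", {
  ts <- euler_maruyama(cubic_model(1, 1, 0.5),
                       sim_spec(dt = 0.01, n_steps = 1e6, seed = 10,
                                initial_state = 1))
  cfg <- fit_config(stride = 5, seed = 10, maxit = 300)
  path <- ssr(polynomial_library(5, "odd", "drift"),
              polynomial_library(2, "even", "diffusion"), ts, cfg)
  # each level drops exactly one term
  sizes <- vapply(path$levels, function(l) length(l$active), integer(1))
  expect_identical(sizes, seq(5L, 1L))
  sel <- path$levels[[path$selected_index]]
  expect_setequal(sel$active, c("f:x", "f:x^3", "s:1"))
  expect_equal(sel$model$drift_coeffs[1], 1, tolerance = 0.15)
  expect_equal(sel$model$drift_coeffs[2], -1, tolerance = 0.15)
  # the path cost jumps once a true term is removed
  expect_gt(path$path_costs[path$selected_index + 1],
            2 * min(path$path_costs))
  # determinism of the path
  path2 <- ssr(polynomial_library(5, "odd", "drift"),
               polynomial_library(2, "even", "diffusion"), ts, cfg)
  expect_identical(lapply(path$levels, `[[`, "active"),
                   lapply(path2$levels, `[[`, "active"))
  expect_identical(path$selected_index, path2$selected_index)
})

test_that("ssr validates its configuration", {
  ts <- langevin_ts(rnorm(1000), 0.1)
  expect_error(
    ssr(polynomial_library(3, "odd", "drift"),
        polynomial_library(0, "all", "diffusion"),
        ts, fit_config()),            # no stride set
    class = "invalid_argument"
  )
})
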