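test_that("euler_maruyama degenerates correctly without noise", {
  # sigma = 0 would be flagged infeasible by the fitting machinery but is a
  # legal simulation: forward Euler.
  det <- langevin_model(
    polynomial_library(3, "odd", "drift"), c(1, -1),
    polynomial_library(0, "all", "diffusion"), 0
  )
  ts <- euler_maruyama(det, sim_spec(dt = 0.01, n_steps = 2000,
                                     initial_state = 0.1, burn_in = 0))
  expect_equal(ts$values[1], 0.1)
  expect_equal(ts$values[2000], 1, tolerance = 1e-3)  # pitchfork attractor
  # f = 0, sigma = 0: constant
  cst <- langevin_model(
    polynomial_library(1, "odd", "drift"), 0,
    polynomial_library(0, "all", "diffusion"), 0
  )
  ts0 <- euler_maruyama(cst, sim_spec(n_steps = 100, initial_state = 0.7,
                                      burn_in = 0))
  expect_true(all(ts0$values == 0.7))
})

test_that("OU long-run variance matches sigma^2/(2 theta)", {
  theta <- 2; s <- 1
  ts <- euler_maruyama(ou_model(theta, s),
                       sim_spec(dt = 0.005, n_steps = 1e6, seed = 1))
  expect_equal(var(ts$values), s^2 / (2 * theta), tolerance = 0.05)
  # halving dt moves the estimate by less than the Monte-Carlo error
  ts2 <- euler_maruyama(ou_model(theta, s),
                        sim_spec(dt = 0.0025, n_steps = 1e6, seed = 1))
  expect_equal(var(ts2$values), var(ts$values), tolerance = 0.05)
})

test_that("simulations are bitwise-reproducible given the seed", {
  spec <- sim_spec(dt = 0.01, n_steps = 5000, seed = 99, substeps = 10)
  a <- simulate_colored_pitchfork(spec = spec)
  b <- simulate_colored_pitchfork(spec = spec)
  expect_identical(a$values, b$values)
  c1 <- simulate_colored_pitchfork(spec = sim_spec(dt = 0.01, n_steps = 5000,
                                                   seed = 100, substeps = 10))
  expect_false(identical(a$values, c1$values))
})

test_that("coloured pitchfork: deterministic limit and noise scales", {
  # sigma_eta = 0: deterministic relaxation to the attractor at +1
  ts <- simulate_colored_pitchfork(
    sigma_eta = 0,
    spec = sim_spec(dt = 0.01, n_steps = 3000, initial_state = 0.1,
                    burn_in = 0, substeps = 10))
  expect_equal(ts$values[3000], 1, tolerance = 1e-3)
  # benchmark condition: bistable switching with statistical +/- symmetry
  tsb <- simulate_colored_pitchfork(
    spec = sim_spec(dt = 0.01, n_steps = 5e5, seed = 2, substeps = 10))
  expect_gt(sum(tsb$values > 0.5), 1000)
  expect_gt(sum(tsb$values < -0.5), 1000)
  expect_lt(abs(mean(tsb$values)), 0.5)
  # OU forcing scale: eta sd ~ sigma_eta / sqrt(2 alpha) ~ 3.5; the slow
  # variable responds with excursions of order 0.5 around the wells
  expect_lt(sd(tsb$values), 1.5)
})

test_that("double-well generator honours its deterministic structure", {
  # noiseless: relaxes to +sqrt(eps)
  ts <- simulate_double_well(eps = 1, sigma = 0,
                             spec = sim_spec(dt = 0.01, n_steps = 5000,
                                             initial_state = c(2, 0),
                                             burn_in = 0))
  expect_equal(ts$values[5000], 1, tolerance = 1e-3)
  # unstable equilibrium at the origin is preserved exactly by symmetry
  ts0 <- simulate_double_well(eps = 5, sigma = 0,
                              spec = sim_spec(dt = 0.01, n_steps = 100,
                                              initial_state = c(0, 0),
                                              burn_in = 0))
  expect_true(all(ts0$values == 0))
  # eps = 20 with the default forcing rule: bistable switching
  tsb <- simulate_double_well(eps = 20,
                              spec = sim_spec(dt = 0.01, n_steps = 5e5,
                                              seed = 5,
                                              initial_state = c(sqrt(20), 0)))
  expect_gt(sum(tsb$values > 2), 1000)
  expect_gt(sum(tsb$values < -2), 1000)
})

test_that("wake surrogate returns a nonnegative radius with the right limit", {
  # noiseless: r -> sqrt(lambda/mu)
  ts <- simulate_wake_surrogate(lambda = 1, mu = 4, sigma0 = 1e-12, sigma1 = 0,
                                spec = sim_spec(dt = 0.01, n_steps = 3000,
                                                initial_state = c(2, 0),
                                                burn_in = 0))
  expect_equal(ts$values[3000], 0.5, tolerance = 1e-3)
  tsn <- simulate_wake_surrogate(
    spec = sim_spec(dt = 0.01, n_steps = 1e5, seed = 7,
                    initial_state = c(1, 0)))
  expect_true(all(tsn$values >= 0))
})

test_that("dwell_times implements a hysteresis detector", {
  # square wave of period 2T -> all dwells equal T
  sq <- langevin_ts(rep(c(1, 1, 1, 1, -1, -1, -1, -1), 50), 0.5)
  d <- dwell_times(sq, 0.5, -0.5)
  expect_true(all(d == 2))  # 4 samples * dt 0.5
  # monotone series: no switches
  expect_length(dwell_times(langevin_ts(1:100, 1), 50, 25), 0)
  # telegraph process with rate k: exponential dwells, mean 1/k
  set.seed(17)
  k <- 0.5
  n_flip <- 400
  dur <- rexp(n_flip, k)
  dtv <- 0.01
  x <- rep(rep(c(1, -1), length.out = n_flip), times = pmax(1, round(dur / dtv)))
  d2 <- dwell_times(langevin_ts(x, dtv), 0.5, -0.5)
  expect_equal(mean(d2), 1 / k, tolerance = 0.15)
  # chatter around one threshold does not create spurious switches; the
  # censored pre-switch interval is dropped
  chat <- langevin_ts(c(1, 0.4, 0.8, 0.3, 0.9, -1, 1), 1)
  expect_length(dwell_times(chat, 0.7, -0.7), 1)
})

test_that("power_spectrum locates peaks and matches the OU Lorentzian", {
  dt <- 0.01
  tt <- (0:(2^15 - 1)) * dt
  f0 <- 2.5
  ps <- power_spectrum(langevin_ts(sin(2 * pi * f0 * tt) + 1e-6 * rnorm(2^15), dt),
                       segment_length = 4096)
  expect_equal(ps$frequency[which.max(ps$power)], f0, tolerance = 1 / (4096 * dt) * 1.5)
  # white noise: flat; total power ~ variance
  set.seed(23)
  w <- langevin_ts(rnorm(2^16), dt)
  pw <- power_spectrum(w, segment_length = 1024)
  expect_equal(sum(pw$power) * (pw$frequency[2] - pw$frequency[1]), 1,
               tolerance = 0.1)
  expect_lt(sd(pw$power) / mean(pw$power), 0.5)
  # OU spectrum: one-sided Lorentzian 2 s^2 / (theta^2 + (2 pi f)^2)
  theta <- 1; s <- 1
  ou <- euler_maruyama(ou_model(theta, s),
                       sim_spec(dt = 0.02, n_steps = 2^19, seed = 29))
  po <- power_spectrum(ou, segment_length = 2^12)
  f <- po$frequency[2:200]
  lorentz <- 2 * s^2 / (theta^2 + (2 * pi * f)^2)
  ratio <- po$power[2:200] / lorentz
  expect_equal(median(ratio), 1, tolerance = 0.2)
  expect_error(power_spectrum(w, segment_length = 2^20),
               class = "invalid_argument")
})
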