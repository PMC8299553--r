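#' Fitting configuration
#'
#' Collects every tunable of the Langevin-regression optimization loop.
#'
#' @param stride Subsampling stride `l` (tau = l*dt), or `NA` to require the
#'   caller to choose (e.g. via [markov_scan()]).
#' @param eta KL regularization weight, or `"auto"` to set it to the power
#'   of ten nearest the minimum of the unregularized (`eta = 0`) cost, so
#'   the moment and density terms enter with roughly equal weight.
#' @param eta_floor Floor used by the automatic rule when the unregularized
#'   cost is (near) zero.
#' @param n_bins,trim Data-grid settings (see [data_grid()]).
#' @param min_count Minimum pairs per bin (see [estimate_moments()]).
#' @param weights Bin weight rule, `"stderr"` or `"uniform"`.
#' @param extend Operator grid extension fraction.
#' @param pdf_method Stationary-density solver for the KL term.
#' @param maxit,reltol Nelder-Mead iteration cap and relative convergence
#'   tolerance.
#' @param restarts Number of simplex restarts (1-3): from the no-adjoint
#'   baseline estimate, from twice it, and from a seeded random
#'   perturbation of it.
#' @param perturb_sd Relative scale of the random-restart perturbation.
#' @param infeasibility_penalty Finite cost assigned to infeasible models.
#' @param knee_factor Model-selection rule: smallest model whose refitted
#'   cost is within this factor of the minimum cost along the path.
#' @param seed Integer seed making fits and paths reproducible.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(stride = NA_integer_, eta = "auto", eta_floor = 1e-6,
                       n_bins = 40L, trim = 5e-4, min_count = 10L,
                       weights = "stderr", extend = 0.25,
                       pdf_method = "analytic",
                       maxit = 500L, reltol = 1e-8, restarts = 3L,
                       perturb_sd = 0.25,
                       infeasibility_penalty = 1e10,
                       knee_factor = 2, seed = 0L) {
  if (!identical(eta, "auto") && (!is.numeric(eta) || eta < 0)) {
    lr_error("'eta' must be \"auto\" or a non-negative number", "invalid_argument")
  }
  if (maxit < 1L) lr_error("'maxit' must be >= 1", "invalid_argument")
  structure(as.list(environment()), class = "fit_config")
}

# Shared preprocessing: subsample -> grid -> binned moments + empirical pdf.
# The grid spans the trimmed percentile range of the subsampled data.
prepare_fit_data <- function(ts, config) {
  plan <- sampling_plan(config$stride)
  sub <- subsample(ts, plan)
  grid <- data_grid(sub, n_bins = config$n_bins, trim = config$trim)
  binned <- estimate_moments(ts, grid, plan, min_count = config$min_count,
                             weights = config$weights)
  p_hat <- empirical_pdf(sub, grid)
  list(plan = plan, grid = grid, binned = binned, p_hat = p_hat)
}

# Core coefficient optimization on precomputed data. 'active_*' masks fix
# removed terms at zero (for SSR). Returns a fit_result.
fit_core <- function(structure_model, binned, p_hat, eta, config,
                     active_drift = NULL, active_diff = NULL,
                     init = NULL) {
  nf <- length(structure_model$drift_coeffs)
  ns <- length(structure_model$diffusion_coeffs)
  if (is.null(active_drift)) active_drift <- rep(TRUE, nf)
  if (is.null(active_diff)) active_diff <- rep(TRUE, ns)
  npar <- sum(active_drift) + sum(active_diff)
  if (npar < 1L) lr_error("no free coefficients to fit", "invalid_argument")

  # Clamp the model to the grid extent used for the discretization.
  structure_model$domain <- range(structure_model$domain, binned$grid$edges,
                                  na.rm = TRUE)
  if (structure_model$polar_ito_term) {
    structure_model$domain[1] <- max(structure_model$domain[1], 1e-12)
  }

  n_eval <- 0L
  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    m <- set_coefficients(structure_model, theta, active_drift, active_diff)
    total_cost(m, binned, p_hat, eta = eta,
               pdf_method = config$pdf_method, extend = config$extend,
               infeasibility_penalty = config$infeasibility_penalty)$total
  }

  if (is.null(init)) {
    base <- tryCatch(
      fit_no_adjoint_core(structure_model, binned,
                          active_drift, active_diff),
      error = function(e) NULL
    )
    if (is.null(base)) base <- rep(0.1, npar)
    starts <- list(base)
    if (config$restarts >= 2L) starts <- c(starts, list(2 * base))
    if (config$restarts >= 3L) {
      pert <- base * (1 + config$perturb_sd * rnorm(npar)) +
        config$perturb_sd * 0.01 * rnorm(npar)
      starts <- c(starts, list(pert))
    }
  } else {
    starts <- if (is.list(init)) init else list(init)
  }

  best <- NULL
  for (st in starts) {
    opt <- if (npar == 1L) {
      # Nelder-Mead is unreliable in 1D; use Brent on a generous bracket.
      width <- max(1, 10 * abs(st))
      o <- stats::optim(st, objective, method = "Brent",
                        lower = st - width, upper = st + width,
                        control = list(maxit = config$maxit))
      o
    } else {
      stats::optim(st, objective, method = "Nelder-Mead",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$value >= config$infeasibility_penalty) {
    lr_error("all optimizer restarts ended infeasible", "fit_failure")
  }

  model <- set_coefficients(structure_model, best$par, active_drift, active_diff)
  cost <- total_cost(model, binned, p_hat, eta = eta,
                     pdf_method = config$pdf_method, extend = config$extend,
                     infeasibility_penalty = config$infeasibility_penalty)
  structure(
    list(model = model, cost = cost,
         converged = is.null(best$convergence) || best$convergence == 0L,
         n_evaluations = n_eval,
         active_drift = active_drift, active_diff = active_diff),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$model)
  print(x$cost)
  cat(sprintf("  %d cost evaluations\n", x$n_evaluations))
  invisible(x)
}

#' Choose the KL weight automatically
#'
#' Runs an unregularized (`eta = 0`) fit and returns the power of ten
#' nearest its minimum cost, floored at `config$eta_floor`, so the moment
#' and density terms carry roughly equal weight in the total cost.
#'
#' @param structure_model A `langevin_model` giving the structure (its
#'   coefficients are starting guesses only).
#' @param binned A `binned_moments`.
#' @param p_hat An `empirical_pdf`.
#' @param config A `fit_config`.
#' @return A positive scalar `eta`.
#' @export
choose_eta <- function(structure_model, binned, p_hat, config = fit_config()) {
  f0 <- fit_core(structure_model, binned, p_hat, eta = 0, config = config)
  nearest_pow10(f0$cost$total, floor = config$eta_floor)
}

#' Fit a Langevin model to a time series
#'
#' The full Langevin-regression pipeline for a fixed model structure:
#' subsample at the configured stride, bin, estimate empirical finite-time
#' conditional moments and the empirical density, select the KL weight
#' `eta` (if `"auto"`), and minimize the total cost over the model
#' coefficients with a restarted Nelder-Mead simplex search. The restarts
#' are warm-started from the no-adjoint baseline estimate, which is
#' typically within a factor of a few of the optimum. Deterministic given
#' `config$seed`.
#'
#' @param structure_model A `langevin_model` defining libraries, polar flag
#'   and domain; its coefficient values are ignored.
#' @param ts A `langevin_ts`.
#' @param config A `fit_config` with a concrete `stride`.
#' @return A `fit_result`: optimized `model`, `cost` breakdown, `converged`
#'   flag, `n_evaluations`, plus the `binned`, `p_hat` and `eta` used.
#' @export
fit_langevin <- function(structure_model, ts, config = fit_config()) {
  stopifnot(inherits(structure_model, "langevin_model"),
            inherits(ts, "langevin_ts"))
  if (is.na(config$stride)) {
    lr_error("config$stride must be set (use markov_scan() to choose one)",
             "invalid_argument")
  }
  set.seed(config$seed)
  dat <- prepare_fit_data(ts, config)
  eta <- if (identical(config$eta, "auto")) {
    choose_eta(structure_model, dat$binned, dat$p_hat, config)
  } else config$eta
  res <- fit_core(structure_model, dat$binned, dat$p_hat, eta, config)
  res$binned <- dat$binned
  res$p_hat <- dat$p_hat
  res$eta <- eta
  res
}

# Linearized no-adjoint baseline on precomputed bins (supports SSR masks).
# Diffusion: sigma_hat(x_i) = sqrt(m2_i / tau) regressed onto the sigma
# library; drift: m1_i/tau (minus the structural polar term computed from
# the fitted sigma) regressed onto the drift library. Weighted by w2 / w1.
fit_no_adjoint_core <- function(structure_model, binned,
                                active_drift = NULL, active_diff = NULL) {
  nf <- length(structure_model$drift_coeffs)
  ns <- length(structure_model$diffusion_coeffs)
  if (is.null(active_drift)) active_drift <- rep(TRUE, nf)
  if (is.null(active_diff)) active_diff <- rep(TRUE, ns)
  v <- binned$valid
  x <- binned$grid$centers[v]
  tau <- binned$tau

  xs <- numeric(ns)
  theta_s <- numeric(0)
  if (any(active_diff)) {
    Xs <- library_matrix(structure_model$diffusion_library, x)[, active_diff,
                                                               drop = FALSE]
    ys <- sqrt(pmax(binned$m2[v], 0) / tau)
    ws <- binned$w2[v]
    fit_s <- stats::lm.wfit(Xs, ys, ws)
    if (any(!is.finite(fit_s$coefficients))) {
      lr_error("diffusion library rank-deficient on the valid bins", "fit_failure")
    }
    theta_s <- fit_s$coefficients
    xs[active_diff] <- theta_s
  }

  theta_f <- numeric(0)
  if (any(active_drift)) {
    Xf <- library_matrix(structure_model$drift_library, x)[, active_drift,
                                                           drop = FALSE]
    yf <- binned$m1[v] / tau
    if (structure_model$polar_ito_term) {
      sig <- drop(library_matrix(structure_model$diffusion_library, x) %*% xs)
      yf <- yf - sig^2 / (2 * x)
    }
    wf <- binned$w1[v]
    fit_f <- stats::lm.wfit(Xf, yf, wf)
    if (any(!is.finite(fit_f$coefficients))) {
      lr_error("drift library rank-deficient on the valid bins", "fit_failure")
    }
    theta_f <- fit_f$coefficients
  }
  as.numeric(c(theta_f, theta_s))
}

#' Baseline fit without the adjoint correction
#'
#' Direct weighted linear least squares of the small-`tau` Kramers-Moyal
#' estimates onto the libraries: `m1/tau` onto the drift candidates and
#' `sqrt(m2/tau)` (the implied noise amplitude) onto the diffusion
#' candidates, with no finite-sampling-time correction. At coarse strides
#' this systematically underestimates the true coefficients; it is the
#' uncorrected reference the adjoint machinery improves on, and also serves
#' as the optimizer warm start.
#'
#' @inheritParams fit_langevin
#' @return A `fit_result` (with `eta = 0` and the uncorrected cost of the
#'   returned model).
#' @export
fit_no_adjoint <- function(structure_model, ts, config = fit_config()) {
  stopifnot(inherits(structure_model, "langevin_model"),
            inherits(ts, "langevin_ts"))
  if (is.na(config$stride)) lr_error("config$stride must be set", "invalid_argument")
  dat <- prepare_fit_data(ts, config)
  theta <- fit_no_adjoint_core(structure_model, dat$binned)
  model <- set_coefficients(structure_model, theta)
  model$domain <- range(model$domain, dat$grid$edges)
  cost <- total_cost(model, dat$binned, dat$p_hat, eta = 0,
                     pdf_method = config$pdf_method, extend = config$extend,
                     infeasibility_penalty = config$infeasibility_penalty)
  structure(
    list(model = model, cost = cost, converged = TRUE,
         n_evaluations = 1L, binned = dat$binned, p_hat = dat$p_hat,
         eta = 0),
    class = "fit_result"
  )
}
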