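#' Parameterized Langevin model
#'
#' Represents the scalar stochastic differential equation
#' `dx = f(x) dt + sigma(x) dW` with drift `f` and noise amplitude `sigma`
#' expanded over candidate function libraries. The effective diffusion is
#' `a(x) = sigma(x)^2 / 2`. For radial-coordinate models
#' (`polar_ito_term = TRUE`) the drift additionally carries the structural,
#' coefficient-free Ito term `sigma(r)^2 / (2 r)` arising from the change of
#' variables of an isotropic planar system to polar coordinates; it is
#' recomputed from the current diffusion coefficients at every evaluation and
#' is never a sparsification candidate.
#'
#' @param drift_library,diffusion_library `function_library` objects.
#' @param drift_coeffs,diffusion_coeffs Numeric coefficient vectors, one per
#'   library term.
#' @param polar_ito_term Logical; include the structural `sigma^2/(2r)` drift
#'   term. Requires a strictly positive domain.
#' @param domain Length-2 numeric, the closed interval on which the model may
#'   be evaluated. Evaluation outside it is an error, not an extrapolation.
#' @return An object of class `"langevin_model"`.
#' @examples
#' m <- pitchfork_model(lambda = 1, mu = 1, sigma = 0.5)
#' evaluate_drift(m, c(-1, 0, 1, 2)) # 0 0 0 -6
#' @export
langevin_model <- function(drift_library, drift_coeffs,
                           diffusion_library, diffusion_coeffs,
                           polar_ito_term = FALSE,
                           domain = c(-Inf, Inf)) {
  stopifnot(inherits(drift_library, "function_library"),
            inherits(diffusion_library, "function_library"))
  if (length(drift_coeffs) != length(drift_library)) {
    lr_error("length(drift_coeffs) must match the drift library", "invalid_argument")
  }
  if (length(diffusion_coeffs) != length(diffusion_library)) {
    lr_error("length(diffusion_coeffs) must match the diffusion library",
             "invalid_argument")
  }
  if (length(domain) != 2L || !is.numeric(domain) || domain[1] >= domain[2]) {
    lr_error("'domain' must be an increasing length-2 numeric", "invalid_argument")
  }
  if (isTRUE(polar_ito_term) && domain[1] <= 0) {
    lr_error("polar models require a strictly positive domain (r > 0)",
             "domain_error")
  }
  structure(
    list(
      drift_library = drift_library,
      drift_coeffs = as.numeric(drift_coeffs),
      diffusion_library = diffusion_library,
      diffusion_coeffs = as.numeric(diffusion_coeffs),
      polar_ito_term = isTRUE(polar_ito_term),
      domain = as.numeric(domain)
    ),
    class = "langevin_model"
  )
}

#' @export
print.langevin_model <- function(x, ...) {
  fmt <- function(lib, co) paste(sprintf("%+.4g*%s", co, names(lib)), collapse = " ")
  cat("<langevin_model>\n")
  cat("  drift:     ", fmt(x$drift_library, x$drift_coeffs),
      if (x$polar_ito_term) " + sigma(r)^2/(2r)" else "", "\n", sep = "")
  cat("  diffusion: ", fmt(x$diffusion_library, x$diffusion_coeffs), "\n", sep = "")
  cat(sprintf("  domain:    [%g, %g]\n", x$domain[1], x$domain[2]))
  invisible(x)
}

#' Convenience constructors for the benchmark model families
#'
#' `pitchfork_model()` builds `f(x) = lambda*x - mu*x^3` with constant noise
#' amplitude `sigma`. `wake_model()` builds the radial pitchfork
#' `f(r) = lambda*r - mu*r^3 + sigma(r)^2/(2r)` with
#' `sigma(r) = sigma0 + sigma1*r^2` (structural Ito term included).
#'
#' @param lambda,mu Drift coefficients of the pitchfork normal form.
#' @param sigma Constant noise amplitude.
#' @param sigma0,sigma1 Coefficients of the quadratic noise amplitude.
#' @param domain Model domain (positive for `wake_model`).
#' @return A `langevin_model`.
#' @export
pitchfork_model <- function(lambda = 1, mu = 1, sigma = 0.5,
                            domain = c(-Inf, Inf)) {
  langevin_model(
    drift_library = polynomial_library(3, "odd", "drift"),
    drift_coeffs = c(lambda, -mu),
    diffusion_library = polynomial_library(0, "all", "diffusion"),
    diffusion_coeffs = sigma,
    domain = domain
  )
}

#' @rdname pitchfork_model
#' @export
wake_model <- function(lambda = 1, mu = 1, sigma0 = 0.4, sigma1 = 0.2,
                       domain = c(1e-8, Inf)) {
  langevin_model(
    drift_library = polynomial_library(3, "odd", "drift"),
    drift_coeffs = c(lambda, -mu),
    diffusion_library = polynomial_library(2, "even", "diffusion"),
    diffusion_coeffs = c(sigma0, sigma1),
    polar_ito_term = TRUE,
    domain = domain
  )
}

check_in_domain <- function(model, x) {
  if (any(x < model$domain[1] | x > model$domain[2])) {
    lr_error("evaluation point outside the model domain", "domain_error")
  }
}

#' Evaluate drift and diffusion of a Langevin model
#'
#' `evaluate_drift()` returns `f(x)` including the structural polar Ito term
#' when set; `evaluate_diffusion()` returns the noise amplitude `sigma(x)`.
#' `evaluate_a()` returns the diffusion `a(x) = sigma(x)^2/2`. If `sigma`
#' is not strictly positive at every queried point, `evaluate_diffusion()`
#' signals a (catchable, non-fatal) warning of class `"infeasible_model"`
#' and still returns the values; the fitting routines convert this signal
#' into a finite penalty.
#'
#' @param model A `langevin_model`.
#' @param x Numeric vector of evaluation points inside the model domain.
#' @param check_feasible Logical; signal on non-positive `sigma`.
#' @return Numeric vector, same length as `x`.
#' @export
evaluate_drift <- function(model, x) {
  check_in_domain(model, x)
  f <- drop(library_matrix(model$drift_library, x) %*% model$drift_coeffs)
  if (model$polar_ito_term) {
    if (any(x == 0)) lr_error("polar Ito term undefined at r = 0", "domain_error")
    s <- drop(library_matrix(model$diffusion_library, x) %*% model$diffusion_coeffs)
    f <- f + s^2 / (2 * x)
  }
  f
}

#' @rdname evaluate_drift
#' @export
evaluate_diffusion <- function(model, x, check_feasible = TRUE) {
  check_in_domain(model, x)
  s <- drop(library_matrix(model$diffusion_library, x) %*% model$diffusion_coeffs)
  if (check_feasible && any(s <= 0)) {
    lr_infeasible(sprintf(
      "sigma(x) <= 0 at %d of %d queried point(s); model infeasible there",
      sum(s <= 0), length(x)))
  }
  s
}

#' @rdname evaluate_drift
#' @export
evaluate_a <- function(model, x, check_feasible = TRUE) {
  evaluate_diffusion(model, x, check_feasible = check_feasible)^2 / 2
}

# TRUE iff sigma(x) > 0 at every point (no condition signalled).
model_feasible <- function(model, x) {
  s <- drop(library_matrix(model$diffusion_library, x) %*% model$diffusion_coeffs)
  all(is.finite(s)) && all(s > 0)
}

# Replace the free coefficients of a model; used by the optimizer. 'theta'
# is the concatenation (drift coeffs, diffusion coeffs) restricted to the
# active terms given by logical masks.
set_coefficients <- function(model, theta,
                             active_drift = NULL, active_diff = NULL) {
  nf <- length(model$drift_coeffs)
  ns <- length(model$diffusion_coeffs)
  if (is.null(active_drift)) active_drift <- rep(TRUE, nf)
  if (is.null(active_diff)) active_diff <- rep(TRUE, ns)
  stopifnot(length(theta) == sum(active_drift) + sum(active_diff))
  xf <- numeric(nf); xs <- numeric(ns)
  xf[active_drift] <- theta[seq_len(sum(active_drift))]
  xs[active_diff] <- theta[sum(active_drift) + seq_len(sum(active_diff))]
  model$drift_coeffs <- xf
  model$diffusion_coeffs <- xs
  model
}
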