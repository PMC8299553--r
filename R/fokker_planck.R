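#' Discretized forward and adjoint Fokker-Planck operators
#'
#' For the Langevin model `dx = f dt + sigma dW` the probability density
#' obeys `dp/dt = -d/dx(f p) + d^2/dx^2(a p) = L p` with `a = sigma^2/2`,
#' while observables evolve under the adjoint generator
#' `L+ = f d/dx + a d^2/dx^2`. The forward operator is discretized in
#' conservative (flux) form with zero-flux boundaries, so discrete
#' probability is conserved exactly (column sums of `L` vanish); the
#' adjoint is discretized independently with second-order central
#' differences in the interior and second-order one-sided stencils at the
#' two boundary points.
#'
#' @param model A feasible `langevin_model` (`sigma > 0` on the grid).
#' @param grid A `grid1d`; operators act on fields sampled at its centers.
#' @return Object of class `"grid_operators"`: `grid`, `forward`, `adjoint`
#'   (dense matrices), `f`, `a` (drift/diffusion at the centers).
#' @export
build_operators <- function(model, grid) {
  x <- grid$centers
  n <- grid$n_bins
  h <- grid$h
  f <- evaluate_drift(model, x)
  s <- evaluate_diffusion(model, x, check_feasible = FALSE)
  if (any(!is.finite(s)) || any(s <= 0)) {
    lr_infeasible("sigma(x) <= 0 on the operator grid")
  }
  a <- s^2 / 2

  # Adjoint: L+ g = f g' + a g''.
  Ladj <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    Ladj[i, i - 1] <- -f[i] / (2 * h) + a[i] / h^2
    Ladj[i, i]     <- -2 * a[i] / h^2
    Ladj[i, i + 1] <-  f[i] / (2 * h) + a[i] / h^2
  }
  # One-sided second-order stencils at the boundary points:
  # g'(x1)  ~ (-3 g1 + 4 g2 - g3) / (2h)
  # g''(x1) ~ ( 2 g1 - 5 g2 + 4 g3 - g4) / h^2
  Ladj[1, 1:4] <- f[1] * c(-3, 4, -1, 0) / (2 * h) +
    a[1] * c(2, -5, 4, -1) / h^2
  Ladj[n, n - (3:0)] <- f[n] * c(0, 1, -4, 3) / (2 * h) +
    a[n] * c(-1, 4, -5, 2) / h^2

  # Forward, finite-volume flux form: dp_i/dt = -(J_{i+1/2} - J_{i-1/2})/h
  # with J_{i+1/2} = fbar*(p_i + p_{i+1})/2 - (a_{i+1} p_{i+1} - a_i p_i)/h
  # and zero flux through the outer faces.
  L <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    fb <- (f[i] + f[i + 1]) / 2
    # Flux J_{i+1/2} as a row over (p_i, p_{i+1}):
    ci <- fb / 2 + a[i] / h
    cj <- fb / 2 - a[i + 1] / h
    # -J/h into cell i, +J/h into cell i+1.
    L[i, i]         <- L[i, i]         - ci / h
    L[i, i + 1]     <- L[i, i + 1]     - cj / h
    L[i + 1, i]     <- L[i + 1, i]     + ci / h
    L[i + 1, i + 1] <- L[i + 1, i + 1] + cj / h
  }

  structure(
    list(grid = grid, forward = L, adjoint = Ladj, f = f, a = a),
    class = "grid_operators"
  )
}

#' Exact finite-time conditional moments of a model
#'
#' Propagates the observables `x` and `x^2` through the adjoint
#' Fokker-Planck semigroup `exp(tau L+)` (dense scaling-and-squaring matrix
#' exponential) and assembles the conditional moments of the increment over
#' a sampling interval `tau`:
#' `m1(x) = w1(x,tau) - x` and `m2(x) = w2(x,tau) - 2 x w1(x,tau) + x^2`,
#' where `w_n(x,t)` solves the adjoint equation with initial condition
#' `x^n`. These are the model-implied counterparts of the binned empirical
#' moments, exact at finite `tau` — this is the correction that undoes the
#' distortion introduced by coarse subsampling.
#'
#' The operators are built on the data grid extended by `extend` of its
#' span on each side (same spacing) to keep boundary artifacts away from
#' the data bins; the returned moments are restricted to the original grid
#' centers.
#'
#' @param model A `langevin_model`.
#' @param grid The data `grid1d` on which moments are wanted.
#' @param tau Sampling interval (>= 0).
#' @param extend Fractional one-sided grid extension (default 0.25).
#' @return Object of class `"finite_time_moments"`: `grid`, `tau`, `m1`,
#'   `m2`, plus the propagated fields `w1`, `w2` on the extended grid.
#' @export
finite_time_moments <- function(model, grid, tau, extend = 0.25) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    lr_error("'tau' must be a non-negative scalar", "invalid_argument")
  }
  floor_x <- if (model$polar_ito_term) max(0, model$domain[1] - grid$h) else -Inf
  ext <- extend_grid(grid, frac = extend, floor = floor_x)
  xg <- ext$grid$centers

  if (tau == 0) {
    z <- numeric(grid$n_bins)
    return(structure(
      list(grid = grid, tau = 0, m1 = z, m2 = z, w1 = xg, w2 = xg^2),
      class = "finite_time_moments"
    ))
  }

  # The extended grid may leave the declared model domain; evaluate the
  # libraries there anyway (polynomials extend smoothly) by widening the
  # domain for operator construction only.
  op_model <- model
  op_model$domain <- range(op_model$domain, xg)
  ops <- build_operators(op_model, ext$grid)

  E <- as.matrix(Matrix::expm(Matrix::Matrix(tau * ops$adjoint)))
  if (any(!is.finite(E))) {
    lr_error("matrix exponential overflowed (tau * a / h^2 too large)",
             "numerical_failure")
  }
  w1 <- drop(E %*% xg)
  w2 <- drop(E %*% (xg^2))
  m1 <- w1 - xg
  m2 <- w2 - 2 * xg * w1 + xg^2

  structure(
    list(grid = grid, tau = tau,
         m1 = m1[ext$index], m2 = m2[ext$index],
         w1 = w1, w2 = w2),
    class = "finite_time_moments"
  )
}

#' Stationary density of a Langevin model
#'
#' `stationary_pdf_analytic()` evaluates the 1D zero-flux closed form
#' `p(x) = C / a(x) * exp(int f/a dx)` by cumulative trapezoidal quadrature
#' on the grid (for constant `sigma` this reduces to the familiar
#' `C exp(2/sigma^2 int f dx)`). `stationary_pdf_numeric()` instead takes
#' the null vector of the discretized forward operator (eigenvector of the
#' smallest-magnitude eigenvalue), sign-fixed, tiny negatives clipped, and
#' normalized; it requires the null space to be one-dimensional within
#' tolerance.
#'
#' @param model A feasible `langevin_model`.
#' @param grid A `grid1d`.
#' @return Object of class `"stationary_pdf"`: `grid`, `density` (sums to 1
#'   times the bin width), `source` (`"analytic"` or `"numeric"`).
#' @export
stationary_pdf_analytic <- function(model, grid) {
  x <- grid$centers
  s <- evaluate_diffusion(model, x, check_feasible = FALSE)
  if (any(!is.finite(s)) || any(s <= 0)) lr_infeasible("sigma(x) <= 0 on the grid")
  a <- s^2 / 2
  f <- evaluate_drift(model, x)
  g <- f / a
  # Cumulative trapezoid of f/a from the first center.
  integral <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * diff(x)))
  logp <- integral - log(a)
  logp <- logp - max(logp)  # stabilize before exponentiating
  p <- exp(logp)
  p <- p / (sum(p) * grid$h)
  structure(list(grid = grid, density = p, source = "analytic"),
            class = "stationary_pdf")
}

#' @rdname stationary_pdf_analytic
#' @param tol Tolerance on the scaled residual of the computed null vector
#'   and on the agreement of independent iteration starts.
#' @export
stationary_pdf_numeric <- function(model, grid, tol = 1e-8) {
  ops <- build_operators(model, grid)
  L <- ops$forward
  n <- grid$n_bins
  # Shift-invert (inverse) iteration at 0: the eigenpair of smallest
  # magnitude. A tiny shift regularizes the (numerically singular) factor;
  # convergence is immediate because the spectral gap to the first decaying
  # mode is O(1) while the target eigenvalue is ~0.
  scale <- max(abs(L))
  lu <- tryCatch(Matrix::lu(Matrix::Matrix(L - 1e-12 * scale * diag(n))),
                 error = function(e)
                   lr_error("stationary solve: singular factorization",
                            "solver_failure"))
  iterate <- function(v0) {
    v <- v0
    for (k in 1:4) {
      v <- as.numeric(Matrix::solve(lu, v))
      v <- v / sqrt(sum(v^2))
    }
    if (sum(v) < 0) v <- -v
    v / (sum(v) * grid$h)
  }
  v1 <- iterate(rep(1, n))
  v2 <- iterate(seq(0.5, 1.5, length.out = n))
  if (max(abs(v1 - v2)) > 1e-6 * max(abs(v1))) {
    lr_error("numeric stationary solver: null space dimension > 1 (starting
             vectors converge to different densities)", "solver_failure")
  }
  res <- max(abs(L %*% v1)) / (scale * max(abs(v1)))
  if (!is.finite(res) || res > tol) {
    lr_error("numeric stationary solver: residual too large", "solver_failure")
  }
  # Central differencing of advection-dominated tails (cell Peclet > 2)
  # leaves tiny oscillatory negatives in the exact discrete null vector;
  # clip them, but treat larger negative mass as a failure.
  if (any(v1 < -1e-3 * max(v1))) {
    lr_error("numeric stationary solver: significantly negative density",
             "solver_failure")
  }
  v1[v1 < 0] <- 0
  v1 <- v1 / (sum(v1) * grid$h)
  structure(list(grid = grid, density = v1, source = "numeric"),
            class = "stationary_pdf")
}
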