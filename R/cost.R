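#' Weighted finite-time moment cost
#'
#' The discrepancy between the model-implied finite-time conditional
#' moments (adjoint-corrected, see [finite_time_moments()]) and the binned
#' empirical estimates:
#' `sum_n sum_i w_i^(n) [m_tau^(n)(x_i; xi) - mhat_tau^(n)(x_i)]^2`
#' over valid bins, `n = 1, 2`. An infeasible model (`sigma <= 0` on the
#' operator grid) yields the large finite `infeasibility_penalty` so a
#' simplex search remains well-defined.
#'
#' @param model A `langevin_model`.
#' @param binned A `binned_moments`.
#' @param extend Grid extension fraction passed to [finite_time_moments()].
#' @param infeasibility_penalty Finite cost for infeasible models.
#' @return Non-negative scalar.
#' @export
moment_cost <- function(model, binned, extend = 0.25,
                        infeasibility_penalty = 1e10) {
  stopifnot(inherits(binned, "binned_moments"))
  ftm <- tryCatch(
    withCallingHandlers(
      finite_time_moments(model, binned$grid, binned$tau, extend = extend),
      infeasible_model = function(w) {
        lr_error("infeasible", "infeasible_caught")
      }
    ),
    infeasible_caught = function(e) NULL,
    numerical_failure = function(e) NULL
  )
  if (is.null(ftm)) return(infeasibility_penalty)
  v <- binned$valid
  r1 <- ftm$m1[v] - binned$m1[v]
  r2 <- ftm$m2[v] - binned$m2[v]
  cost <- sum(binned$w1[v] * r1^2) + sum(binned$w2[v] * r2^2)
  if (!is.finite(cost)) infeasibility_penalty else cost
}

#' Kullback-Leibler divergence between binned densities
#'
#' `D_KL(p_hat, p) = sum_i p_hat_i log(p_hat_i / p_i) h` over bins with
#' `p_hat_i > 0`; the model density is floored at 1e-300 inside the
#' logarithm. Non-symmetric and non-negative.
#'
#' @param p_hat An `empirical_pdf` (reference distribution).
#' @param p_model A `stationary_pdf` or `empirical_pdf` on the same grid.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(p_hat, p_model) {
  if (!same_grid(p_hat$grid, p_model$grid)) {
    lr_error("the two densities live on different grids", "invalid_argument")
  }
  ph <- p_hat$density
  pm <- pmax(p_model$density, 1e-300)
  i <- ph > 0
  sum(ph[i] * log(ph[i] / pm[i])) * p_hat$grid$h
}

#' Total Langevin-regression cost
#'
#' Combines the weighted moment residual with the KL divergence between the
#' empirical density and the model's stationary density:
#' `J(xi) = moment_cost + eta * D_KL(p_hat, p(x; xi))`. In one dimension
#' the stationary density has an exact, positivity-preserving closed form,
#' which is the default (`pdf_method = "analytic"`); the numeric
#' null-vector solver (`"numeric"`, with analytic fallback on solver
#' failure) is the route that generalizes beyond 1D.
#'
#' @param model A `langevin_model`.
#' @param binned A `binned_moments`.
#' @param p_hat An `empirical_pdf` on the same grid.
#' @param eta Non-negative KL weight.
#' @param pdf_method `"analytic"` (default) or `"numeric"`.
#' @inheritParams moment_cost
#' @return Object of class `"cost_breakdown"`: `moment_term`, `kl_term`,
#'   `eta`, `total = moment_term + eta * kl_term`.
#' @export
total_cost <- function(model, binned, p_hat, eta = 0,
                       pdf_method = c("analytic", "numeric"),
                       extend = 0.25, infeasibility_penalty = 1e10) {
  pdf_method <- match.arg(pdf_method)
  if (eta < 0) lr_error("'eta' must be non-negative", "invalid_argument")
  mt <- moment_cost(model, binned, extend = extend,
                    infeasibility_penalty = infeasibility_penalty)
  if (mt >= infeasibility_penalty) {
    return(structure(list(moment_term = mt, kl_term = 0, eta = eta, total = mt),
                     class = "cost_breakdown"))
  }
  kl <- 0
  if (eta > 0) {
    pm <- tryCatch(
      suppressWarnings(
        if (pdf_method == "numeric") {
          tryCatch(stationary_pdf_numeric(model, binned$grid),
                   solver_failure = function(e)
                     stationary_pdf_analytic(model, binned$grid))
        } else {
          stationary_pdf_analytic(model, binned$grid)
        }),
      error = function(e) NULL
    )
    if (is.null(pm)) {
      return(structure(
        list(moment_term = infeasibility_penalty, kl_term = 0, eta = eta,
             total = infeasibility_penalty),
        class = "cost_breakdown"))
    }
    kl <- kl_divergence(p_hat, pm)
  }
  structure(
    list(moment_term = mt, kl_term = kl, eta = eta, total = mt + eta * kl),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> total = %.6g (moments %.6g + %g * KL %.6g)\n",
              x$total, x$moment_term, x$eta, x$kl_term))
  invisible(x)
}

# Nearest power of ten to a positive cost value, with a floor for the
# degenerate (zero-cost) case.
nearest_pow10 <- function(c0, floor = 1e-6) {
  if (!is.finite(c0) || c0 <= floor) return(floor)
  10^round(log10(c0))
}
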