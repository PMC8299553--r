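#' Reverse-greedy stepwise sparse regression
#'
#' Structure discovery when the functional form of the model is unknown.
#' Starting from the full candidate model (all drift and diffusion library
#' terms active, plus the structural polar Ito term if requested), the
#' procedure repeatedly refits the model with each currently active term
#' removed in turn and permanently discards the term whose removal yields
#' the smallest refitted total cost — the least important contribution, as
#' measured by the cost itself rather than by coefficient magnitude. The
#' path continues until a single term remains. For a Pareto-optimal model
#' the cost jumps sharply once essential terms start to be discarded; the
#' automatic selection takes the smallest model whose cost stays within
#' `knee_factor` of the path minimum, and the full path is always reported
#' for inspection.
#'
#' `eta` is chosen once on the full model (if `"auto"`) and held fixed along
#' the path so costs are comparable; each level's refit is warm-started from
#' the parent level's coefficients (one simplex start). The structural Ito
#' term is never a removal candidate. Ties in removal cost are broken by
#' discarding the higher-degree term first.
#'
#' @param drift_lib,diff_lib `function_library` objects (combined size >= 2).
#' @param ts A `langevin_ts`.
#' @param config A `fit_config` with a concrete `stride`.
#' @param polar_ito_term Include the structural `sigma^2/(2r)` drift term.
#' @param domain Model domain; defaults to the data-grid extent.
#' @return Object of class `"ssr_path"`: `levels` (list with `active`
#'   term names, `model`, `cost`), `selected_index`, `eta`.
#' @export
ssr <- function(drift_lib, diff_lib, ts, config = fit_config(),
                polar_ito_term = FALSE, domain = NULL) {
  stopifnot(inherits(drift_lib, "function_library"),
            inherits(diff_lib, "function_library"),
            inherits(ts, "langevin_ts"))
  nf <- length(drift_lib)
  ns <- length(diff_lib)
  if (nf + ns < 2L) {
    lr_error("combined library must have at least 2 terms", "invalid_argument")
  }
  if (is.na(config$stride)) lr_error("config$stride must be set", "invalid_argument")
  set.seed(config$seed)

  dat <- prepare_fit_data(ts, config)
  if (is.null(domain)) {
    domain <- range(dat$grid$edges)
    if (polar_ito_term) domain[1] <- max(domain[1], 1e-12)
  }
  structure_model <- langevin_model(
    drift_lib, numeric(nf), diff_lib, numeric(ns),
    polar_ito_term = polar_ito_term, domain = domain
  )

  term_names <- c(paste0("f:", names(drift_lib)), paste0("s:", names(diff_lib)))
  term_degree <- c(library_degrees(drift_lib), library_degrees(diff_lib))
  is_drift <- c(rep(TRUE, nf), rep(FALSE, ns))

  eta <- if (identical(config$eta, "auto")) {
    choose_eta(structure_model, dat$binned, dat$p_hat, config)
  } else config$eta

  refit <- function(active, init = NULL) {
    tryCatch(
      fit_core(structure_model, dat$binned, dat$p_hat, eta, config,
               active_drift = active[is_drift], active_diff = active[!is_drift],
               init = init),
      error = function(e) NULL
    )
  }

  active <- rep(TRUE, nf + ns)
  full <- refit(active)
  if (is.null(full)) lr_error("full-model fit failed", "fit_failure")
  levels <- list(list(active = term_names[active], model = full$model,
                      cost = full$cost))
  current <- full

  while (sum(active) > 1L) {
    cand_idx <- which(active)
    cand <- lapply(cand_idx, function(j) {
      act <- active; act[j] <- FALSE
      # Warm start: parent coefficients restricted to the surviving terms.
      init <- c(current$model$drift_coeffs[act[seq_len(nf)]],
                current$model$diffusion_coeffs[act[nf + seq_len(ns)]])
      refit(act, init = init)
    })
    costs <- vapply(cand, function(r) if (is.null(r)) Inf else r$cost$total,
                    numeric(1))
    # Smallest refitted cost; ties remove the higher-degree term first.
    best <- order(costs, -term_degree[cand_idx])[1L]
    active[cand_idx[best]] <- FALSE
    current <- cand[[best]]
    if (is.null(current)) {
      # All removals failed: record a penalty level and stop.
      levels <- c(levels, list(list(active = term_names[active], model = NULL,
                                    cost = list(total = Inf))))
      break
    }
    levels <- c(levels, list(list(active = term_names[active],
                                  model = current$model, cost = current$cost)))
  }

  path_costs <- vapply(levels, function(l) l$cost$total, numeric(1))
  cmin <- min(path_costs)
  admissible <- which(path_costs <= config$knee_factor * cmin)
  selected_index <- max(admissible)  # latest level = fewest terms

  structure(
    list(levels = levels, selected_index = selected_index, eta = eta,
         path_costs = path_costs, term_names = term_names,
         binned = dat$binned, p_hat = dat$p_hat),
    class = "ssr_path"
  )
}

#' @export
print.ssr_path <- function(x, ...) {
  cat("<ssr_path>\n")
  for (i in seq_along(x$levels)) {
    sel <- if (i == x$selected_index) " <== selected" else ""
    cat(sprintf("  level %d: cost = %.6g  [%s]%s\n", i,
                x$path_costs[i], paste(x$levels[[i]]$active, collapse = ", "),
                sel))
  }
  invisible(x)
}

#' Selected model of an SSR path
#'
#' @param path An `ssr_path`.
#' @return The `langevin_model` at the selected level.
#' @export
selected_model <- function(path) {
  stopifnot(inherits(path, "ssr_path"))
  path$levels[[path$selected_index]]$model
}
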