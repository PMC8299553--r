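#' Run configuration for the end-to-end pipelines
#'
#' A plain named list validated by `run_config()`. Fields: `input` (path to
#' a delimited time-series file), `dt`, `stride` (integer, or `"auto"` with
#' `stride_scan` a vector of candidates for [markov_scan()]), grid and
#' library settings, the [fit_config()] fields, `out_dir` and `verbose`.
#' Configuration may be read from a JSON file with `load_run_config()`;
#' explicitly supplied arguments override file values, which override
#' defaults, and the effective settings of every run are written next to
#' the results so a run can be reproduced exactly.
#'
#' @param input Path to the input series (must exist).
#' @param dt Sampling interval of the input.
#' @param stride Integer stride or `"auto"`.
#' @param stride_scan Candidate strides for the automatic choice.
#' @param drift_degree,drift_parity Drift library settings.
#' @param diff_degree,diff_parity Diffusion library settings.
#' @param polar_ito_term Include the structural radial Ito drift term.
#' @param out_dir Output directory (created if missing).
#' @param verbose Logical.
#' @param ... Overrides for [fit_config()] fields.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input, dt, stride = "auto",
                       stride_scan = c(1L, 5L, 10L, 25L, 50L, 100L),
                       drift_degree = 3L, drift_parity = "odd",
                       diff_degree = 0L, diff_parity = "even",
                       polar_ito_term = FALSE,
                       out_dir = ".", verbose = FALSE, ...) {
  if (!file.exists(input)) {
    lr_error(paste0("input file does not exist: ", input), "configuration_error")
  }
  if (!identical(stride, "auto")) {
    stride <- as.integer(stride)
    if (is.na(stride) || stride < 1L) {
      lr_error("'stride' must be a positive integer or \"auto\"", "configuration_error")
    }
  } else if (length(stride_scan) == 0L) {
    lr_error("stride = \"auto\" requires a non-empty 'stride_scan'",
             "configuration_error")
  }
  fc <- fit_config(...)
  structure(
    c(list(input = input, dt = dt, stride_setting = stride,
           stride_scan = as.integer(stride_scan),
           drift_degree = as.integer(drift_degree), drift_parity = drift_parity,
           diff_degree = as.integer(diff_degree), diff_parity = diff_parity,
           polar_ito_term = isTRUE(polar_ito_term),
           out_dir = out_dir, verbose = isTRUE(verbose)),
      fc),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON configuration file.
#' @export
load_run_config <- function(path, ...) {
  if (!file.exists(path)) {
    lr_error(paste0("config file does not exist: ", path), "configuration_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  overrides <- list(...)
  obj[names(overrides)] <- overrides
  do.call(run_config, obj)
}

resolve_stride <- function(config, ts) {
  if (!identical(config$stride_setting, "auto")) {
    return(list(stride = config$stride_setting, scan = NULL))
  }
  scan <- markov_scan(ts, config$stride_scan)
  stride <- scan$recommended_stride
  if (is.na(stride)) {
    # No candidate decorrelates; take the least-correlated one.
    stride <- scan$strides[which.min(abs(scan$increment_autocorr))]
  }
  list(stride = stride, scan = scan)
}

config_record <- function(config, extra = list()) {
  rec <- config
  class(rec) <- NULL
  rec$stride_setting <- as.character(rec$stride_setting)
  c(rec, extra)
}

build_structure <- function(config, domain = c(-Inf, Inf)) {
  drift_lib <- polynomial_library(config$drift_degree, config$drift_parity,
                                  "drift")
  diff_lib <- polynomial_library(config$diff_degree, config$diff_parity,
                                 "diffusion")
  if (config$polar_ito_term) domain[1] <- max(domain[1], 1e-12)
  langevin_model(drift_lib, numeric(length(drift_lib)),
                 diff_lib, numeric(length(diff_lib)),
                 polar_ito_term = config$polar_ito_term, domain = domain)
}

#' End-to-end fit pipeline
#'
#' Load, choose the stride (scanning if `"auto"`), fit a fixed-structure
#' model by Langevin regression, and write: `model.json`, `moments.csv`
#' (binned vs model-implied moments), `pdf.csv` (empirical vs model
#' stationary density), `cost.json` and `run_record.json` (all effective
#' settings including defaults and the seed).
#'
#' @param config A `run_config`.
#' @return The `fit_result`, invisibly; report files in `config$out_dir`.
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ts <- load_timeseries(config$input, config$dt)
  rs <- resolve_stride(config, ts)
  if (config$verbose) message("stride = ", rs$stride)

  fc <- fit_config(
    stride = rs$stride, eta = config$eta, eta_floor = config$eta_floor,
    n_bins = config$n_bins, trim = config$trim, min_count = config$min_count,
    weights = config$weights, extend = config$extend,
    pdf_method = config$pdf_method, maxit = config$maxit,
    reltol = config$reltol, restarts = config$restarts,
    perturb_sd = config$perturb_sd,
    infeasibility_penalty = config$infeasibility_penalty,
    knee_factor = config$knee_factor, seed = config$seed
  )
  structure_model <- build_structure(config)
  res <- fit_langevin(structure_model, ts, fc)

  out <- function(f) file.path(config$out_dir, f)
  save_model(res$model, out("model.json"))
  ftm <- finite_time_moments(res$model, res$binned$grid, res$binned$tau,
                             extend = config$extend)
  mom <- data.frame(
    bin_center = res$binned$grid$centers, count = res$binned$counts,
    m1_hat = res$binned$m1, m2_hat = res$binned$m2,
    m1_model = ftm$m1, m2_model = ftm$m2,
    w1 = res$binned$w1, w2 = res$binned$w2, valid = res$binned$valid
  )
  write.table(mom, out("moments.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  pm <- stationary_pdf_analytic(res$model, res$binned$grid)
  pdf_tab <- data.frame(x = res$binned$grid$centers,
                        empirical = res$p_hat$density, model = pm$density)
  write.table(pdf_tab, out("pdf.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(moment_term = res$cost$moment_term, kl_term = res$cost$kl_term,
         eta = res$eta, total = res$cost$total,
         converged = res$converged, n_evaluations = res$n_evaluations),
    out("cost.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    config_record(config, list(
      effective_stride = rs$stride,
      stride_scan_autocorr = if (is.null(rs$scan)) NULL else
        as.list(stats::setNames(rs$scan$increment_autocorr,
                                rs$scan$strides)))),
    out("run_record.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' End-to-end model selection pipeline
#'
#' Runs the reverse-greedy stepwise sparse regression over the configured
#' libraries and writes `path.csv` (per-level active set and cost),
#' `selected_model.json` and `run_record.json`. Reruns with the same seed
#' produce an identical path file.
#'
#' @param config A `run_config`.
#' @return The `ssr_path`, invisibly.
#' @export
run_select <- function(config) {
  stopifnot(inherits(config, "run_config"))
  drift_lib <- polynomial_library(config$drift_degree, config$drift_parity, "drift")
  diff_lib <- polynomial_library(config$diff_degree, config$diff_parity, "diffusion")
  if (length(drift_lib) == 1L && length(diff_lib) == 1L) {
    lr_error("model selection needs more than one candidate per component",
             "configuration_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ts <- load_timeseries(config$input, config$dt)
  rs <- resolve_stride(config, ts)

  fc <- fit_config(
    stride = rs$stride, eta = config$eta, eta_floor = config$eta_floor,
    n_bins = config$n_bins, trim = config$trim, min_count = config$min_count,
    weights = config$weights, extend = config$extend,
    pdf_method = config$pdf_method, maxit = config$maxit,
    reltol = config$reltol, restarts = config$restarts,
    perturb_sd = config$perturb_sd,
    infeasibility_penalty = config$infeasibility_penalty,
    knee_factor = config$knee_factor, seed = config$seed
  )
  path <- ssr(drift_lib, diff_lib, ts, fc,
              polar_ito_term = config$polar_ito_term)

  out <- function(f) file.path(config$out_dir, f)
  tab <- data.frame(
    level = seq_along(path$levels),
    n_terms = vapply(path$levels, function(l) length(l$active), integer(1)),
    active = vapply(path$levels, function(l) paste(l$active, collapse = "+"),
                    character(1)),
    cost = path$path_costs,
    selected = seq_along(path$levels) == path$selected_index
  )
  write.table(tab, out("path.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  save_model(selected_model(path), out("selected_model.json"))
  jsonlite::write_json(
    config_record(config, list(effective_stride = rs$stride, eta = path$eta)),
    out("run_record.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
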