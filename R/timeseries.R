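#' Uniformly sampled time series
#'
#' The universal input object: an ordered sequence of scalar states sampled
#' every `dt` time units.
#'
#' @param values Numeric vector of states (length >= 2, all finite).
#' @param dt Sampling interval (> 0).
#' @param label Optional descriptive string.
#' @return Object of class `"langevin_ts"` with fields `values`, `dt`,
#'   `label`.
#' @export
langevin_ts <- function(values, dt, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) lr_error("time series needs >= 2 samples", "invalid_argument")
  if (!all(is.finite(values))) lr_error("time series contains non-finite values", "invalid_argument")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    lr_error("'dt' must be a positive scalar", "invalid_argument")
  }
  structure(list(values = values, dt = as.numeric(dt), label = as.character(label)),
            class = "langevin_ts")
}

#' @export
length.langevin_ts <- function(x) length(x$values)

#' @export
print.langevin_ts <- function(x, ...) {
  cat(sprintf("<langevin_ts> %d samples, dt = %g%s\n", length(x$values), x$dt,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Subsampling plan
#'
#' Picks every `stride`-th sample, so the effective sampling interval is
#' `tau = stride * dt`. Coarse sampling lets time-correlated ("coloured")
#' forcing decorrelate so the subsampled process is approximately Markovian;
#' the finite-`tau` distortion this introduces is what the adjoint
#' Fokker-Planck correction undoes.
#'
#' @param stride Positive integer decimation factor `l`.
#' @return Object of class `"sampling_plan"` with field `stride`.
#' @export
sampling_plan <- function(stride) {
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1 ||
      stride != round(stride)) {
    lr_error("'stride' must be a positive integer", "invalid_argument")
  }
  structure(list(stride = as.integer(stride)), class = "sampling_plan")
}

plan_tau <- function(plan, ts) plan$stride * ts$dt

#' Decimate a time series
#'
#' @param ts A `langevin_ts`.
#' @param plan A `sampling_plan` (or a bare integer stride).
#' @return A `langevin_ts` with every `stride`-th sample and `dt` scaled by
#'   the stride.
#' @export
subsample <- function(ts, plan) {
  if (is.numeric(plan)) plan <- sampling_plan(plan)
  stopifnot(inherits(ts, "langevin_ts"), inherits(plan, "sampling_plan"))
  if (plan$stride >= length(ts$values)) {
    lr_error("stride must be smaller than the series length", "invalid_argument")
  }
  idx <- seq(1L, length(ts$values), by = plan$stride)
  langevin_ts(ts$values[idx], ts$dt * plan$stride, ts$label)
}
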