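#' Binned finite-time conditional moments
#'
#' Estimates the empirical Kramers-Moyal statistics at lag `tau = stride*dt`:
#' for every transition pair `(x_k, x_{k+l})` assigned to the bin containing
#' `x_k`, the per-bin mean of the increment `D = x_{k+l} - x_k` (first
#' conditional moment `m1`) and the per-bin mean of `D^2` (second *raw*
#' conditional moment `m2`). All overlapping pairs at lag `l` are used.
#' Uncertainty weights are inverse squared standard errors,
#' `w1 = count / var(D)` and `w2 = count / var(D^2)`, floored at machine
#' epsilon in the denominator; bins with fewer than `min_count` pairs are
#' marked invalid and get zero weight.
#'
#' Note `m2` is the raw second moment `<D^2>`, not the centred variance:
#' the adjoint finite-time correction is formulated for raw moments.
#'
#' @param ts A `langevin_ts`.
#' @param grid A `grid1d` covering the bulk of the data.
#' @param plan A `sampling_plan` (or integer stride).
#' @param min_count Minimum pairs per bin for validity (default 10).
#' @param weights `"stderr"` (default) or `"uniform"` (weight 1 on valid bins).
#' @return Object of class `"binned_moments"`: `grid`, `tau`, `m1`, `m2`,
#'   `counts`, `w1`, `w2`, `valid`.
#' @export
estimate_moments <- function(ts, grid, plan, min_count = 10L,
                             weights = c("stderr", "uniform")) {
  weights <- match.arg(weights)
  if (is.numeric(plan)) plan <- sampling_plan(plan)
  stopifnot(inherits(ts, "langevin_ts"), inherits(grid, "grid1d"))
  if (min_count < 1L) lr_error("'min_count' must be >= 1", "invalid_argument")
  l <- plan$stride
  n <- length(ts$values)
  if (l >= n) lr_error("stride must be smaller than the series length", "invalid_argument")
  tau <- l * ts$dt

  x0 <- ts$values[seq_len(n - l)]
  d <- ts$values[(l + 1L):n] - x0
  ib <- bin_index(x0, grid)
  keep <- ib > 0L
  ib <- ib[keep]; d <- d[keep]
  if (length(d) == 0L) lr_error("no transition pairs fall inside the grid", "estimation_failure")

  nb <- grid$n_bins
  counts <- tabulate(ib, nbins = nb)
  d2 <- d * d
  sums <- rowsum(cbind(d, d2, d2 * d2), ib, reorder = TRUE)
  rows <- as.integer(rownames(sums))
  s1 <- s2 <- s4 <- numeric(nb)
  s1[rows] <- sums[, 1L]; s2[rows] <- sums[, 2L]; s4[rows] <- sums[, 3L]

  m1 <- ifelse(counts > 0L, s1 / counts, NA_real_)
  m2 <- ifelse(counts > 0L, s2 / counts, NA_real_)
  var1 <- pmax(m2 - m1^2, 0)
  var2 <- pmax(ifelse(counts > 0L, s4 / counts, NA_real_) - m2^2, 0)

  valid <- counts >= min_count
  if (!any(valid)) lr_error("no bin reaches 'min_count' pairs", "estimation_failure")
  eps <- .Machine$double.eps
  if (weights == "stderr") {
    w1 <- ifelse(valid, counts / pmax(var1, eps), 0)
    w2 <- ifelse(valid, counts / pmax(var2, eps), 0)
  } else {
    w1 <- w2 <- as.numeric(valid)
  }

  structure(
    list(grid = grid, tau = tau, m1 = m1, m2 = m2, counts = counts,
         w1 = w1, w2 = w2, valid = valid),
    class = "binned_moments"
  )
}

#' @export
print.binned_moments <- function(x, ...) {
  cat(sprintf("<binned_moments> tau = %g, %d/%d valid bins, %d pairs\n",
              x$tau, sum(x$valid), x$grid$n_bins, sum(x$counts)))
  invisible(x)
}

#' Empirical stationary density
#'
#' Normalized histogram density on the grid centers. Samples outside the
#' grid are dropped; their count is attached as attribute `"n_dropped"`.
#'
#' @param ts A `langevin_ts` or numeric vector.
#' @param grid A `grid1d`.
#' @return Object of class `"empirical_pdf"`: `grid`, `density` (sums to 1
#'   after multiplying by the bin width).
#' @export
empirical_pdf <- function(ts, grid) {
  x <- if (inherits(ts, "langevin_ts")) ts$values else as.numeric(ts)
  ib <- bin_index(x, grid)
  n_dropped <- sum(ib == 0L)
  ib <- ib[ib > 0L]
  if (length(ib) == 0L) lr_error("all samples fall outside the grid", "estimation_failure")
  counts <- tabulate(ib, nbins = grid$n_bins)
  dens <- counts / (length(ib) * grid$h)
  structure(
    list(grid = grid, density = dens),
    class = "empirical_pdf", n_dropped = n_dropped
  )
}

#' Einstein-Markov subsampling scan
#'
#' For each candidate stride, decimates the series and computes the lag-1
#' autocorrelation of the resulting increment sequence. When unresolved
#' forcing is time-correlated, fast sampling leaves this autocorrelation far
#' from zero; the recommended stride is the smallest one whose increment
#' autocorrelation falls below the threshold in magnitude — a simple proxy
#' for the Einstein-Markov decorrelation scale.
#'
#' @param ts A `langevin_ts`.
#' @param strides Integer vector of candidate strides.
#' @param threshold Absolute autocorrelation below which increments are
#'   considered decorrelated (default 0.05).
#' @return Object of class `"markov_diagnostic"`: `strides`,
#'   `increment_autocorr`, `recommended_stride` (NA if no stride qualifies).
#' @export
markov_scan <- function(ts, strides, threshold = 0.05) {
  stopifnot(inherits(ts, "langevin_ts"))
  if (length(strides) == 0L) lr_error("'strides' must be non-empty", "invalid_argument")
  strides <- sort(unique(as.integer(strides)))
  if (any(strides < 1L)) lr_error("strides must be positive", "invalid_argument")
  if (max(strides) * 3L >= length(ts$values)) {
    lr_error("largest stride too close to the series length", "invalid_argument")
  }
  ac <- vapply(strides, function(l) {
    d <- diff(ts$values[seq(1L, length(ts$values), by = l)])
    a <- d[-length(d)]; b <- d[-1L]
    va <- stats::sd(a) * stats::sd(b)
    if (va == 0) 0 else mean((a - mean(a)) * (b - mean(b))) / va
  }, numeric(1))
  ok <- which(abs(ac) < threshold)
  rec <- if (length(ok)) strides[ok[1L]] else NA_integer_
  if (is.na(rec)) {
    warning("no candidate stride decorrelates the increments below the threshold")
  }
  structure(
    list(strides = strides, increment_autocorr = ac,
         recommended_stride = rec, threshold = threshold),
    class = "markov_diagnostic"
  )
}

#' @export
print.markov_diagnostic <- function(x, ...) {
  cat("<markov_diagnostic>\n")
  print(data.frame(stride = x$strides, autocorr = round(x$increment_autocorr, 4)))
  cat(sprintf("recommended stride: %s (|acf| < %g)\n",
              ifelse(is.na(x$recommended_stride), "none", x$recommended_stride),
              x$threshold))
  invisible(x)
}
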