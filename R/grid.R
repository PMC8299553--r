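#' Uniform 1D grid
#'
#' A uniform binning/collocation grid: `n_bins` cells with `n_bins + 1`
#' edges; bin statistics and Fokker-Planck fields live on the cell centers.
#' The binning convention is half-open `[edge_i, edge_{i+1})` with the final
#' edge closed.
#'
#' @param lo,hi Extent of the grid (`lo < hi`).
#' @param n_bins Number of cells (>= 2).
#' @return Object of class `"grid1d"` with fields `n_bins`, `edges`,
#'   `centers`, `h` (uniform spacing).
#' @export
grid1d <- function(lo, hi, n_bins = 40L) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    lr_error("'lo' must be strictly less than 'hi'", "invalid_argument")
  }
  if (n_bins < 2L) lr_error("'n_bins' must be >= 2", "invalid_argument")
  n_bins <- as.integer(n_bins)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  structure(
    list(n_bins = n_bins,
         edges = edges,
         centers = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
         h = (hi - lo) / n_bins),
    class = "grid1d"
  )
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("<grid1d> %d bins on [%g, %g], h = %g\n",
              x$n_bins, x$edges[1], x$edges[x$n_bins + 1L], x$h))
  invisible(x)
}

#' Default data grid
#'
#' Uniform grid spanning a trimmed percentile range of the data, robust to
#' rare excursions while covering the stationary support.
#'
#' @param ts A `langevin_ts` (or numeric vector).
#' @param n_bins Number of bins (default 40).
#' @param trim Fraction trimmed at each tail (default 5e-4, i.e. the
#'   0.05th-99.95th percentile range).
#' @return A `grid1d`.
#' @export
data_grid <- function(ts, n_bins = 40L, trim = 5e-4) {
  x <- if (inherits(ts, "langevin_ts")) ts$values else as.numeric(ts)
  q <- quantile(x, c(trim, 1 - trim), names = FALSE, type = 7)
  if (q[1] >= q[2]) {
    # Degenerate (near-constant) data: widen symmetrically.
    q <- c(q[1] - 0.5, q[2] + 0.5)
  }
  grid1d(q[1], q[2], n_bins)
}

# Extend a grid by 'frac' of its span on each side, keeping the spacing, so
# boundary artifacts of the adjoint propagation stay away from the data
# bins. Points at or below 'floor' (e.g. r = 0 for polar models) are
# dropped on the left.
extend_grid <- function(grid, frac = 0.25, floor = -Inf) {
  if (frac <= 0) return(list(grid = grid, index = seq_len(grid$n_bins)))
  span <- grid$edges[grid$n_bins + 1L] - grid$edges[1L]
  k <- ceiling(frac * span / grid$h)
  left <- grid$centers[1L] - grid$h * (k:1)
  right <- grid$centers[grid$n_bins] + grid$h * (1:k)
  left <- left[left > floor]
  centers <- c(left, grid$centers, right)
  ext <- structure(
    list(n_bins = length(centers),
         edges = c(centers - grid$h / 2, centers[length(centers)] + grid$h / 2),
         centers = centers,
         h = grid$h),
    class = "grid1d"
  )
  list(grid = ext, index = length(left) + seq_len(grid$n_bins))
}

same_grid <- function(g1, g2, tol = 1e-10) {
  g1$n_bins == g2$n_bins &&
    max(abs(g1$edges - g2$edges)) <= tol * max(1, max(abs(g1$edges)))
}

# Bin assignment: half-open [e_i, e_{i+1}), last edge closed; 0 for points
# outside the grid.
bin_index <- function(x, grid) {
  ib <- findInterval(x, grid$edges, rightmost.closed = TRUE)
  ib[ib < 1L | ib > grid$n_bins] <- 0L
  ib
}
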