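# Probability densities on the periodic orientation domain [0, pi).
# Cell-centered uniform grids; integrals are composite midpoint sums, which
# is the quadrature consistent with the finite-volume solver.

#' Cell-centered grid on the periodic domain
#'
#' @param n number of cells (default 720, i.e. quarter-degree resolution).
#' @return cell-center angles `(i - 1/2) * pi / n`, `i = 1..n`.
#' @export
density_grid <- function(n = 720) {
  (seq_len(n) - 0.5) * pi / n
}

#' Orientation probability density
#'
#' A nonnegative density on `[0, pi)` sampled at cell centers of a uniform
#' grid, normalised so that the midpoint integral equals one.
#'
#' @param values nonnegative density values (1/rad) at the cell centers.
#' @param grid cell-center angles; defaults to [density_grid()] of matching
#'   size.
#' @param time time stamp carried along by solvers (default 0).
#' @param normalize renormalise to unit mass (default `TRUE`).
#' @return an object of class `orientation_density` with fields `grid`,
#'   `values`, `n`, `h` (cell width) and `time`.
#' @export
orientation_density <- function(values, grid = NULL, time = 0,
                                normalize = TRUE) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 cells")
  if (is.null(grid)) grid <- density_grid(n)
  if (length(grid) != n) stop("grid/values length mismatch")
  if (any(!is.finite(values))) stop("non-finite density values")
  if (any(values < 0)) {
    if (min(values) < -1e-12 * max(abs(values))) {
      stop("negative density values")
    }
    values <- pmax(values, 0)
  }
  h <- pi / n
  if (normalize) {
    mass <- sum(values) * h
    if (mass <= 0) stop("zero total mass")
    values <- values / mass
  }
  structure(list(grid = grid, values = values, n = n, h = h, time = time),
            class = "orientation_density")
}

#' Uniform density on `[0, pi)`
#'
#' @param n number of cells.
#' @param time time stamp.
#' @return an `orientation_density` equal to `1/pi` everywhere.
#' @export
uniform_density <- function(n = 720, time = 0) {
  orientation_density(rep(1 / pi, n), time = time, normalize = FALSE)
}

#' Midpoint integral of a density (or of a weighted density)
#'
#' @param f an `orientation_density`.
#' @param weights optional weights evaluated at the grid (same length).
#' @return `sum(weights * values) * h`, i.e. the midpoint quadrature of
#'   `integral w(theta) f(theta) dtheta` over `[0, pi)`.
#' @export
integrate_density <- function(f, weights = NULL) {
  if (is.null(weights)) sum(f$values) * f$h else sum(weights * f$values) * f$h
}

#' L1 distance between two densities on a common grid
#'
#' @param f,g `orientation_density` objects on identical grids.
#' @return `integral |f - g| dtheta`.
#' @export
l1_distance <- function(f, g) {
  if (f$n != g$n) stop("densities live on different grids")
  sum(abs(f$values - g$values)) * f$h
}

#' @export
print.orientation_density <- function(x, ...) {
  cat(sprintf(
    "Orientation density on [0, pi): %d cells, mass = %.8f, time = %g\n",
    x$n, sum(x$values) * x$h, x$time))
  s <- summary_stats(x)
  cat(sprintf("  mode = %.2f deg, linear mean = %.2f deg, sd = %.2f deg\n",
              s$mode_deg, s$linear_mean_deg, s$sd_deg))
  invisible(x)
}

#' @export
as.data.frame.orientation_density <- function(x, ...) {
  data.frame(theta_deg = to_degrees(x$grid), density_per_rad = x$values)
}

#' @export
plot.orientation_density <- function(x, ...) {
  graphics::plot(to_degrees(x$grid), x$values, type = "l",
                 xlab = "orientation (deg)", ylab = "density (1/rad)", ...)
}
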