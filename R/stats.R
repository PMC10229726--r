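# Circular and first-quadrant linear statistics of orientation densities.
#
# Experimental work reports orientations over [0, 90] degrees; the model's
# densities live on [0, pi) and are symmetric about pi/2 (F4), so the
# first-quadrant linear mean is 2 * integral_0^{pi/2} theta f dtheta, the
# factor 2 accounting for renormalisation over the quadrant.  Quadrature is
# composite midpoint on the density grid; the quadrant integral weights any
# cell straddling pi/2 by the covered fraction.

# per-cell weight of the [0, pi/2) restriction
.quadrant_weights <- function(f) {
  lower <- f$grid - f$h / 2
  pmin(pmax((pi / 2 - lower) / f$h, 0), 1)
}

.is_quadrant_density <- function(f) {
  abs(f$n * f$h - pi / 2) < 1e-9
}

# integral_0^{pi/2} w(theta) f(theta) dtheta
.quadrant_integral <- function(f, weights = 1) {
  if (.is_quadrant_density(f)) {
    sum(weights * f$values) * f$h
  } else {
    sum(weights * f$values * .quadrant_weights(f)) * f$h
  }
}

# renormalisation factor for quadrant averages; warns on asymmetry
.quadrant_norm <- function(f, warn = TRUE) {
  if (.is_quadrant_density(f)) return(1)
  q <- .quadrant_integral(f)
  if (abs(q - 0.5) > 0.005) {
    if (warn) {
      warning(sprintf(
        "density is asymmetric: integral over [0, pi/2) = %.4f (expected ",
        q), "0.5 under F4 symmetry); renormalising explicitly")
    }
    q
  } else {
    0.5
  }
}

#' First-quadrant circular mean
#'
#' `arctan( integral_0^{pi/2} sin(theta) f dtheta /
#' integral_0^{pi/2} cos(theta) f dtheta )`, in `[0, pi/2]`.  The
#' restriction to the first quadrant is what makes the statistic
#' informative: over the full bimodal density the symmetric sine/cosine
#' moments would always give pi/2.
#'
#' @param f an `orientation_density` (on `[0, pi)` or already folded).
#' @return the circular mean in radians.
#' @export
circular_mean_quadrant <- function(f) {
  s <- .quadrant_integral(f, sin(f$grid))
  c <- .quadrant_integral(f, cos(f$grid))
  if (abs(s) < 1e-300 && abs(c) < 1e-300) {
    stop("undefined circular mean: vanishing trigonometric moments")
  }
  atan2(s, c)
}

#' First-quadrant linear mean and variance
#'
#' `linear_mean = 2 integral_0^{pi/2} theta f dtheta` and
#' `linear_variance = 2 integral_0^{pi/2} (theta - mean)^2 f dtheta`, the
#' averages experimentalists report.  The factor 2 renormalises over the
#' quadrant and presumes the F4 symmetry `f(pi - theta) = f(theta)`; if
#' the quadrant mass deviates from 1/2 by more than 0.5% a warning is
#' raised and the explicit renormalisation `1 / integral_0^{pi/2} f` is
#' used instead.
#'
#' @param f an `orientation_density`.
#' @return the mean in radians (variance in radians squared).
#' @export
linear_mean <- function(f) {
  .quadrant_integral(f, f$grid) / .quadrant_norm(f)
}

#' @rdname linear_mean
#' @export
linear_variance <- function(f) {
  nrm <- .quadrant_norm(f)
  m <- .quadrant_integral(f, f$grid) / nrm
  .quadrant_integral(f, (f$grid - m)^2) / nrm
}

#' Mode of a density
#'
#' @param f an `orientation_density`.
#' @return the grid angle (radians) of the largest density value.
#' @export
density_mode <- function(f) {
  f$grid[which.max(f$values)]
}

#' Summary statistics of an orientation density
#'
#' @param f an `orientation_density`.
#' @return list with circular and linear means, standard deviation and
#'   mode, in radians and degrees.
#' @export
summary_stats <- function(f) {
  cm <- circular_mean_quadrant(f)
  lm <- linear_mean(f)
  lv <- linear_variance(f)
  md <- density_mode(f)
  list(circular_mean = cm, linear_mean = lm, linear_variance = lv, mode = md,
       circular_mean_deg = to_degrees(cm), linear_mean_deg = to_degrees(lm),
       sd_deg = to_degrees(sqrt(lv)), mode_deg = to_degrees(md))
}

#' Calibrate the noise amplitude against a target quadrant mean
#'
#' Scans the stationary linear mean as a function of the effective
#' diffusion `sigma_bar` (log-spaced grid), brackets every crossing of the
#' target, and polishes each root by bisection.  The mean-vs-noise curve
#' runs from `theta_eq` (no noise) through a maximum to `pi/4` (uniform),
#' so up to two `sigma` values can reproduce one target; both are
#' returned, with the stationary peak density as the tie-breaker
#' experimentalists use (match the histogram height).
#'
#' @param target_mean target first-quadrant linear mean (radians, in
#'   `(0, pi/2)`).
#' @param p an [energy_params()] object.
#' @param model `"boltzmann"` (energy drift) or `"control"`.
#' @param regime,lam,omega frequency regime used to convert `sigma_bar`
#'   back to the microscopic `sigma`; see [effective_sigma()].
#' @param sigma_bar_range scanned `sigma_bar` interval.
#' @param n_scan number of log-spaced scan points.
#' @param n grid cells for the stationary densities.
#' @return a data frame with one row per root: `sigma`, `sigma_bar`,
#'   `mean` (radians), `peak` (stationary peak density).  For a flat
#'   mean-vs-sigma curve (the equibiaxial case `r = 1`) the attribute
#'   `flat_branch` is `TRUE` and any `sigma` reproduces the target.
#' @export
calibrate_sigma <- function(target_mean, p,
                            model = c("boltzmann", "control"),
                            regime = c("high", "low"),
                            lam = NULL, omega = NULL,
                            sigma_bar_range = c(1e-3, 10),
                            n_scan = 60, n = 720) {
  model <- match.arg(model)
  regime <- match.arg(regime)
  if (target_mean <= 0 || target_mean >= pi / 2) {
    stop("target mean must lie in (0, pi/2)")
  }
  theta_eq <- if (model == "control") equilibrium_angle(p$alpha, p$r) else NULL
  mean_of <- function(sb) {
    fi <- if (model == "boltzmann") {
      stationary_boltzmann(p, sb, n = n)
    } else {
      stationary_control(theta_eq, sb, n = n)
    }
    linear_mean(fi)
  }
  sb_grid <- exp(seq(log(sigma_bar_range[1]), log(sigma_bar_range[2]),
                     length.out = n_scan))
  means <- vapply(sb_grid, mean_of, numeric(1))
  # conversion sigma_bar -> sigma in the chosen regime
  fac <- 2 * p$eps^2
  if (regime == "low") {
    if (is.null(lam) || is.null(omega)) stop("low regime needs lam and omega")
    fac <- fac * lam * omega
  }
  to_sigma <- function(sb) sqrt(sb^2 * fac)
  if (diff(range(means)) < to_radians(0.05)) {
    if (abs(target_mean - mean(means)) > to_radians(0.5)) {
      stop(sprintf(
        "calibration failure: flat mean curve at %.2f deg cannot reach %.2f deg",
        to_degrees(mean(means)), to_degrees(target_mean)))
    }
    out <- data.frame(sigma = NA_real_, sigma_bar = NA_real_,
                      mean = mean(means), peak = NA_real_)
    attr(out, "flat_branch") <- TRUE
    return(out)
  }
  g <- means - target_mean
  crossings <- which(g[-1] * g[-n_scan] <= 0 & !(g[-1] == 0 & g[-n_scan] == 0))
  exact <- which(g == 0)
  roots <- numeric(0)
  for (k in crossings) {
    if (g[k] == 0) next    # counted via `exact`
    roots <- c(roots, stats::uniroot(function(ls) mean_of(exp(ls)) - target_mean,
                                     lower = log(sb_grid[k]),
                                     upper = log(sb_grid[k + 1]),
                                     tol = 1e-10)$root)
  }
  roots <- sort(unique(c(exp(roots), sb_grid[exact])))
  if (!length(roots)) {
    stop(sprintf(
      "calibration failure: attainable means span [%.2f, %.2f] deg, target %.2f deg",
      to_degrees(min(means)), to_degrees(max(means)),
      to_degrees(target_mean)))
  }
  peak <- vapply(roots, function(sb) {
    fi <- if (model == "boltzmann") {
      stationary_boltzmann(p, sb, n = n)
    } else {
      stationary_control(theta_eq, sb, n = n)
    }
    max(fi$values)
  }, numeric(1))
  out <- data.frame(sigma = to_sigma(roots), sigma_bar = roots,
                    mean = vapply(roots, mean_of, numeric(1)), peak = peak)
  attr(out, "flat_branch") <- FALSE
  out
}

#' Read an experimental orientation histogram
#'
#' Expects a CSV with columns `bin_low_deg`, `bin_high_deg`, `frequency`
#' (the format used to enter published histograms for comparison).
#'
#' @param path path to the CSV file.
#' @return a data frame with the three columns, frequencies renormalised
#'   to sum to one.
#' @export
read_orientation_histogram <- function(path) {
  df <- utils::read.csv(path)
  need <- c("bin_low_deg", "bin_high_deg", "frequency")
  if (!all(need %in% names(df))) {
    stop("histogram CSV needs columns: ", paste(need, collapse = ", "))
  }
  df$frequency <- df$frequency / sum(df$frequency)
  df
}

#' Linear statistics of a binned histogram
#'
#' Mean and standard deviation computed with bin midpoints, matching how
#' experimental quadrant means are defined from binned data.
#'
#' @param hist_df a data frame as returned by [read_orientation_histogram()].
#' @return list with `mean_deg` and `sd_deg`.
#' @export
histogram_stats <- function(hist_df) {
  mid <- (hist_df$bin_low_deg + hist_df$bin_high_deg) / 2
  w <- hist_df$frequency / sum(hist_df$frequency)
  m <- sum(mid * w)
  list(mean_deg = m, sd_deg = sqrt(sum((mid - m)^2 * w)))
}
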