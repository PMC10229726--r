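# Orthotropic elastic energy of a stretched cell and its bifurcation analysis.
#
# The substratum strain tensor is E = diag(eps, -r*eps); the cell's elastic
# response is orthotropic with stiffness ratios k_perp = K_perp/K_par and
# k_s = K_s/K_par (K_par is normalised to 1 throughout, so the dimensional
# prefactor K_par*eps^2 enters drifts only through eps^2).  All angles are
# radians internally; degrees are offered at I/O boundaries via to_degrees().

#' Convert between radians and degrees
#'
#' Orientation angles are radians internally; experimental work reports
#' degrees, so every user-facing summary offers both.
#'
#' @param x numeric vector of angles.
#' @return the converted angles.
#' @export
to_degrees <- function(x) x * 180 / pi

#' @rdname to_degrees
#' @export
to_radians <- function(x) x * pi / 180

#' Anisotropy parameter from stiffness ratios
#'
#' `alpha = (1 + k_perp - k_s) / (1 - k_perp)`.  This single dimensionless
#' combination, together with the biaxiality ratio `r`, controls which
#' equilibrium-orientation scenario the energy landscape falls into.
#'
#' @param k_perp perpendicular-to-parallel stiffness ratio (> 0, != 1).
#' @param k_s shear-to-parallel stiffness ratio (> 0).
#' @return the anisotropy parameter `alpha`.
#' @export
alpha_from_stiffness <- function(k_perp, k_s) {
  if (any(k_perp == 1)) {
    stop("singular parameters: k_perp = 1 makes alpha undefined")
  }
  (1 + k_perp - k_s) / (1 - k_perp)
}

#' Perpendicular stiffness ratio from the anisotropy parameter
#'
#' Inverts [alpha_from_stiffness()]: `k_perp = (k_s - 1 + alpha)/(1 + alpha)`.
#' Positivity of `k_perp` requires the compatibility condition
#' `k_s > 1 - alpha`; the construction fails otherwise.
#'
#' @param k_s shear-to-parallel stiffness ratio (> 0).
#' @param alpha anisotropy parameter.
#' @return the perpendicular stiffness ratio `k_perp`.
#' @export
k_perp_from_alpha <- function(k_s, alpha) {
  if (any(k_s <= 1 - alpha)) {
    stop("compatibility condition violated: need k_s > 1 - alpha ",
         "(got k_s = ", format(k_s), ", alpha = ", format(alpha), ")")
  }
  (k_s - 1 + alpha) / (1 + alpha)
}

#' Bifurcation threshold ratio
#'
#' `rho(alpha) = (1 + alpha)/(1 - alpha)`.  For `alpha` strictly between 0
#' and 1 the oblique-equilibrium scenario (Case 1) occupies biaxiality
#' ratios `r` in `[1/rho, rho]`; `1/rho` is the bifurcation value of `r`
#' below which the perpendicular orientation takes over.
#'
#' @param alpha anisotropy parameter (!= 1).
#' @return `rho(alpha)`.
#' @seealso [bifurcation_r()] for the reciprocal `1/rho`.
#' @export
rho_alpha <- function(alpha) {
  if (any(alpha == 1)) stop("singular parameters: alpha = 1")
  (1 + alpha) / (1 - alpha)
}

#' @rdname rho_alpha
#' @export
bifurcation_r <- function(alpha) {
  if (any(alpha == -1)) stop("singular parameters: alpha = -1")
  (1 - alpha) / (1 + alpha)
}

#' Parameters of the orthotropic elastic energy
#'
#' Collects the biaxiality ratio `r`, the strain amplitude `eps`, and the
#' stiffness ratios, caching the derived anisotropy parameter `alpha`.
#' Exactly one of `k_perp` or `alpha` must be supplied (experimental fits
#' usually fix `alpha` and vary `k_s`, so the `(k_s, alpha)` constructor is
#' the common route; `k_perp` then follows from [k_perp_from_alpha()]).
#'
#' @param r biaxiality ratio (>= 0): the compressive principal strain is
#'   `-r * eps`.
#' @param eps strain amplitude (mean strain over an oscillation period,
#'   dimensionless, >= 0).
#' @param k_s shear stiffness ratio, default 0.7 (its value barely affects
#'   the shape of the stationary distributions).
#' @param k_perp perpendicular stiffness ratio, or `NULL` to derive it.
#' @param alpha anisotropy parameter, or `NULL` to derive it.
#' @return an object of class `energy_params`.
#' @examples
#' p <- energy_params(r = 0.4, eps = 0.2, k_s = 0.7, alpha = 0.794)
#' p$k_perp
#' @export
energy_params <- function(r, eps, k_s = 0.7, k_perp = NULL, alpha = NULL) {
  stopifnot(is.numeric(r), length(r) == 1L, r >= 0,
            is.numeric(eps), length(eps) == 1L, eps >= 0,
            is.numeric(k_s), length(k_s) == 1L, k_s > 0)
  if (is.null(k_perp) && is.null(alpha)) {
    stop("supply one of k_perp or alpha")
  }
  if (is.null(k_perp)) {
    k_perp <- k_perp_from_alpha(k_s, alpha)
  } else if (is.null(alpha)) {
    alpha <- alpha_from_stiffness(k_perp, k_s)
  } else if (abs(alpha_from_stiffness(k_perp, k_s) - alpha) > 1e-8) {
    stop("inconsistent (k_perp, k_s, alpha) triple")
  }
  if (k_perp <= 0) stop("k_perp must be positive (compatibility condition)")
  structure(list(r = r, eps = eps, k_perp = k_perp, k_s = k_s, alpha = alpha),
            class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Orthotropic elastic energy parameters\n")
  cat(sprintf("  r = %g, eps = %g, k_perp = %.4f, k_s = %g, alpha = %.4f\n",
              x$r, x$eps, x$k_perp, x$k_s, x$alpha))
  cl <- classify_case(x$alpha, x$r)
  cat(sprintf("  Case %d; stable equilibria (deg): %s\n", cl$case_id,
              paste(round(to_degrees(cl$equilibria), 2), collapse = ", ")))
  invisible(x)
}

#' Dimensionless orthotropic elastic energy
#'
#' Evaluates
#' `U(theta) = 1/2 * ( [(r+1) cos 2theta + 1 - r]^2
#'   + k_perp [(r+1) cos 2theta - 1 + r]^2
#'   + k_s (r+1)^2 (1 - cos^2 2theta) )`,
#' the stored elastic energy per unit `K_par * eps^2` of a cell oriented at
#' angle `theta` to the main stretch direction.  Depends on `theta` only
#' through `cos 2theta`, hence is automatically pi-periodic and even
#' (the U1 symmetry: `U(theta) = U(pi - theta) = U(pi + theta)`).
#'
#' @param theta angle(s) in radians (any real).
#' @param p an [energy_params()] object.
#' @return the dimensionless energy, vectorised over `theta`.
#' @export
energy_bar <- function(theta, p) {
  c2 <- cos(2 * theta)
  A <- p$r + 1
  0.5 * ((A * c2 + 1 - p$r)^2 +
           p$k_perp * (A * c2 - 1 + p$r)^2 +
           p$k_s * A^2 * (1 - c2^2))
}

#' Derivative of the dimensionless elastic energy
#'
#' Analytic `dU/dtheta`; it is the (negative of the) drift of the
#' overdamped reorientation law and vanishes at every equilibrium as well
#' as at the symmetry points 0, pi/2, pi.
#'
#' @inheritParams energy_bar
#' @return `dU/dtheta`, vectorised over `theta`.
#' @export
energy_bar_deriv <- function(theta, p) {
  c2 <- cos(2 * theta)
  A <- p$r + 1
  dU_dc <- A * (A * c2 + 1 - p$r) +
    p$k_perp * A * (A * c2 - 1 + p$r) -
    p$k_s * A^2 * c2
  -2 * sin(2 * theta) * dU_dc
}

#' Classify the equilibrium-orientation scenario
#'
#' Partitions the `(alpha, r)` plane into the four bifurcation cases of the
#' energy landscape and returns the stable equilibria in `[0, 2*pi)`:
#' \describe{
#'   \item{Case 1}{oblique equilibria `theta_eq, pi - theta_eq,
#'     pi + theta_eq, 2*pi - theta_eq` with `theta_eq` in `(0, pi/2)`;
#'     holds for all `r` when `alpha > 1` and for
#'     `r` in `[1/rho(alpha), rho(alpha)]` when `alpha` in `(0, 1)`.}
#'   \item{Case 2}{`0, pi/2, pi, 3*pi/2` all stable; for all `r` when
#'     `alpha < -1` and for `r` between `rho(alpha)` and `1/rho(alpha)`
#'     when `alpha` in `(-1, 0)`.}
#'   \item{Case 3}{perpendicular orientation only: `pi/2, 3*pi/2`.}
#'   \item{Case 4}{parallel orientation only: `0, pi`.}
#' }
#' Boundary values of `r` belong to Cases 1/2 (the intervals are closed).
#'
#' @param alpha anisotropy parameter.
#' @param r biaxiality ratio (>= 0).
#' @return an object of class `case_label`: a list with `case_id`
#'   (integer 1--4) and `equilibria` (radians in `[0, 2*pi)`).
#' @export
classify_case <- function(alpha, r) {
  stopifnot(length(alpha) == 1L, length(r) == 1L, r >= 0)
  case_id <- if (alpha >= 1) {
    1L
  } else if (alpha <= -1) {
    2L
  } else if (alpha > 0) {
    r_lo <- bifurcation_r(alpha)   # = 1/rho(alpha), computed consistently
    r_hi <- rho_alpha(alpha)
    if (r >= r_lo && r <= r_hi) 1L else if (r < r_lo) 3L else 4L
  } else if (alpha < 0) {
    r_lo <- rho_alpha(alpha)       # in (0, 1)
    r_hi <- bifurcation_r(alpha)
    if (r >= r_lo && r <= r_hi) 2L else if (r < r_lo) 3L else 4L
  } else {                    # alpha == 0: degenerate pitchfork at r = 1
    if (r == 1) 1L else if (r < 1) 3L else 4L
  }
  equilibria <- switch(case_id,
    {
      te <- equilibrium_angle(alpha, r)
      c(te, pi - te, pi + te, 2 * pi - te)
    },
    c(0, pi / 2, pi, 3 * pi / 2),
    c(pi / 2, 3 * pi / 2),
    c(0, pi))
  structure(list(case_id = case_id, equilibria = equilibria),
            class = "case_label")
}

#' @export
print.case_label <- function(x, ...) {
  cat(sprintf("Case %d; stable equilibria (deg): %s\n", x$case_id,
              paste(round(to_degrees(x$equilibria), 2), collapse = ", ")))
  invisible(x)
}

#' Closed-form oblique equilibrium orientation (Case 1)
#'
#' `theta_eq = 1/2 * acos( (1/alpha) * (r - 1)/(r + 1) )`, the unique
#' stable equilibrium in `(0, pi/2)` of the Case-1 energy landscape.  For
#' `r = 1` this is `pi/4` regardless of `alpha` (equibiaxial symmetry).
#'
#' @param alpha anisotropy parameter.
#' @param r biaxiality ratio.
#' @return the equilibrium angle in radians.
#' @export
equilibrium_angle <- function(alpha, r) {
  stopifnot(length(alpha) == 1L, length(r) == 1L)
  if (r == 1) return(pi / 4)
  if (alpha == 0) stop("not Case 1: alpha = 0 has no oblique equilibrium")
  arg <- (1 / alpha) * (r - 1) / (r + 1)
  if (abs(arg) > 1) {
    stop("not Case 1: |(1/alpha)(r-1)/(r+1)| = ", format(abs(arg)), " > 1")
  }
  0.5 * acos(arg)
}
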