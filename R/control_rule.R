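# The optimal-control reorientation target.
#
# A cell at orientation theta reorients toward
#   theta_hat(theta) = theta_eq * p(theta) + (1 - p(theta)) * (pi - theta_eq),
# a convex combination of the two oblique equilibria weighted by p(theta).
# The weight must satisfy seven endpoint conditions:
#   p(theta_eq) = 1, p(pi - theta_eq) = 0, p(0) = p(pi/2) = p(pi) = 1/2,
#   p'(theta_eq) = p'(pi - theta_eq) = 0,
# so that theta_hat fixes both equilibria and sends the symmetry points
# 0, pi/2, pi to the midpoint pi/2 (equal probability of either side).
# A single quadratic cannot satisfy all seven conditions; the minimal-degree
# construction is a 4-piece quadratic spline on
# [0, te], [te, pi/2], [pi/2, pi - te], [pi - te, pi), C1 at the equilibria.

# piece table: on [lo, hi], p(theta) = A + B * (theta - x0)^2
.p_pieces <- function(theta_eq) {
  te <- theta_eq
  q <- pi / 2 - te
  list(lo = c(0, te, pi / 2, pi - te),
       hi = c(te, pi / 2, pi - te, pi),
       A  = c(1, 1, 0, 0),
       B  = c(-1 / (2 * te^2), -1 / (2 * q^2), 1 / (2 * q^2), 1 / (2 * te^2)),
       x0 = c(te, te, pi - te, pi - te))
}

.check_theta_eq <- function(theta_eq) {
  if (length(theta_eq) != 1L || !is.finite(theta_eq) ||
      theta_eq <= 0 || theta_eq >= pi / 2) {
    stop("not Case 1: theta_eq must lie strictly inside (0, pi/2)")
  }
}

#' Reorientation weight p(theta)
#'
#' Piecewise-quadratic weight used by the optimal-control rule; see
#' [theta_hat()].  Satisfies `p(theta_eq) = 1`, `p(pi - theta_eq) = 0`,
#' `p(0) = p(pi/2) = p(pi) = 1/2` and has vanishing derivative at both
#' equilibria.  It obeys the mirror antisymmetry `p(pi - theta) = 1 - p(theta)`.
#'
#' @param theta angle(s); wrapped into `[0, pi)`.
#' @param theta_eq the Case-1 equilibrium angle, strictly in `(0, pi/2)`.
#' @return weights in `[0, 1]`, vectorised over `theta`.
#' @export
p_weight <- function(theta, theta_eq) {
  .check_theta_eq(theta_eq)
  th <- theta %% pi
  pc <- .p_pieces(theta_eq)
  idx <- pmin(findInterval(th, pc$lo), 4L)
  pmin(pmax(pc$A[idx] + pc$B[idx] * (th - pc$x0[idx])^2, 0), 1)
}

#' Optimal-control reorientation target
#'
#' `theta_hat(theta) = theta_eq p(theta) + (1 - p(theta)) (pi - theta_eq)`.
#' Fixed points are exactly the two oblique equilibria; the symmetry points
#' 0, pi/2, pi map to pi/2.  The range is the interval between `theta_eq`
#' and `pi - theta_eq` (convex combination).
#'
#' @inheritParams p_weight
#' @return target angles, vectorised over `theta`.
#' @export
theta_hat <- function(theta, theta_eq) {
  p <- p_weight(theta, theta_eq)
  theta_eq * p + (1 - p) * (pi - theta_eq)
}

# integral_0^theta p(s) ds, piecewise closed form (theta in [0, pi])
.p_cumint <- function(theta, theta_eq) {
  pc <- .p_pieces(theta_eq)
  seg <- function(th, k) {          # integral over [lo_k, th] within piece k
    pc$A[k] * (th - pc$lo[k]) +
      pc$B[k] / 3 * ((th - pc$x0[k])^3 - (pc$lo[k] - pc$x0[k])^3)
  }
  full <- vapply(1:4, function(k) seg(pc$hi[k], k), numeric(1))
  base <- c(0, cumsum(full))        # cumulative at piece lower ends
  idx <- pmin(findInterval(theta, pc$lo), 4L)
  base[idx] + seg(theta, idx)
}

#' Cumulative drift integral of the control rule
#'
#' `integral_0^theta (theta_hat(s) - s) ds`, evaluated in closed form from
#' the piecewise-quadratic weight.  It vanishes at `theta = 0` and, by the
#' mirror antisymmetry of `theta_hat(s) - s` about `pi/2`, at `theta = pi`,
#' which makes the control stationary density periodic.
#'
#' @param theta angle(s) in `[0, pi]` (wrapped modulo pi, with `pi` kept).
#' @param theta_eq the Case-1 equilibrium angle.
#' @return the cumulative integral, vectorised over `theta`.
#' @export
theta_hat_cumint <- function(theta, theta_eq) {
  .check_theta_eq(theta_eq)
  th <- ifelse(theta == pi, pi, theta %% pi)
  # integral theta_hat = (pi - te) * th + (2 te - pi) * integral p
  (pi - theta_eq) * th + (2 * theta_eq - pi) * .p_cumint(th, theta_eq) -
    th^2 / 2
}
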