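# Forward Fokker-Planck solver on the periodic domain [0, pi).
#
# Both drift models fit one flux form
#   dF/dt = d/dtheta [ V'(theta) f + sigma_bar^2 df/dtheta ],
# with V the dimensionless elastic energy (energy drift) or the control
# potential V(theta) = -integral_0^theta (theta_hat - s) ds (control drift),
# in the nondimensional time t_bar = t * eps^2 / lambda_theta.
#
# Spatial scheme: conservative finite volumes with exponentially fitted
# (Chang-Cooper-type) interface coefficients,
#   F_{i+1/2} = sigma_bar^2 / h * ( f_{i+1} e^{(V_{i+1} - V_{i+1/2})/sb2}
#                                 - f_i     e^{(V_i     - V_{i+1/2})/sb2} ),
# so the discrete stationary state is the Boltzmann form exactly at the
# nodes (the interface exponentials telescope).  The exponents involve only
# local potential differences, so they stay small on any reasonable grid.
# Time stepping is backward Euler on the resulting linear operator, which
# is unconditionally stable, conserves mass exactly (the operator's columns
# sum to zero) and preserves positivity (M-matrix).

#' Effective dimensionless diffusion amplitude
#'
#' In the high-frequency regime (`lambda * omega >> 1`)
#' `sigma_bar^2 = sigma^2 / (2 eps^2)`; in the low-frequency regime
#' viscous effects rescale the drift so that
#' `sigma_bar^2 = sigma^2 / (2 lambda omega eps^2)`.  Decreasing the
#' stretch amplitude or the frequency therefore broadens the stationary
#' distribution.
#'
#' @param sigma noise amplitude of the microscopic process.
#' @param eps strain amplitude (> 0).
#' @param regime `"high"` or `"low"` frequency regime.
#' @param lam viscoelastic relaxation time (s); required for `"low"`.
#' @param omega stretch frequency (Hz); required for `"low"`.
#' @return `sigma_bar` (not squared).
#' @examples
#' effective_sigma(0.04, 0.2)^2        # 0.02
#' effective_sigma(0.2, 0.1, "low", lam = 100, omega = 0.001)^2  # 2
#' @export
effective_sigma <- function(sigma, eps, regime = c("high", "low"),
                            lam = NULL, omega = NULL) {
  regime <- match.arg(regime)
  if (eps <= 0) stop("undefined scaling: eps must be positive")
  s2 <- sigma^2 / (2 * eps^2)
  if (regime == "low") {
    if (is.null(lam) || is.null(omega) || lam * omega <= 0) {
      stop("low-frequency regime requires lam * omega > 0")
    }
    s2 <- s2 / (lam * omega)
  }
  sqrt(s2)
}

#' Drift specification for the Fokker-Planck solver
#'
#' Bundles the pi-periodic potential whose gradient drives the drift with
#' the effective diffusion amplitude.  `kind = "energy"` uses the elastic
#' energy [energy_bar()]; `kind = "control"` uses the potential of the
#' optimal-control rule, whose gradient is `-(theta_hat(theta) - theta)`.
#'
#' @param kind `"energy"` or `"control"`.
#' @param sigma_bar effective diffusion amplitude (> 0); see
#'   [effective_sigma()].
#' @param p an [energy_params()] object (required for `"energy"`; for
#'   `"control"` it supplies `theta_eq` unless given directly).
#' @param theta_eq Case-1 equilibrium angle for the control drift.
#' @return an object of class `drift_spec` with a `potential` function.
#' @export
drift_spec <- function(kind = c("energy", "control"), sigma_bar,
                       p = NULL, theta_eq = NULL) {
  kind <- match.arg(kind)
  if (sigma_bar <= 0) {
    stop("degenerate diffusion: sigma_bar = 0 gives a Dirac stationary ",
         "state concentrated at the stable equilibria; use sigma_bar > 0")
  }
  if (kind == "energy") {
    if (is.null(p)) stop("energy drift needs energy_params")
    potential <- function(theta) energy_bar(theta, p)
  } else {
    if (is.null(theta_eq)) {
      if (is.null(p)) stop("control drift needs theta_eq or energy_params")
      theta_eq <- equilibrium_angle(p$alpha, p$r)
    }
    .check_theta_eq(theta_eq)
    force(theta_eq)
    potential <- function(theta) -theta_hat_cumint(theta, theta_eq)
  }
  structure(list(kind = kind, potential = potential, sigma_bar = sigma_bar,
                 p = p, theta_eq = theta_eq),
            class = "drift_spec")
}

#' Boltzmann stationary state of the energy-drift dynamics
#'
#' `f_inf(theta) = C exp(-U(theta) / sigma_bar^2)` on `[0, pi)`, normalised
#' by midpoint quadrature.  Its modes sit at the energy minima; as
#' `sigma_bar -> Inf` it flattens to the uniform density `1/pi`.
#'
#' @param p an [energy_params()] object.
#' @param sigma_bar effective diffusion amplitude (> 0).
#' @param n number of grid cells.
#' @return an `orientation_density`.
#' @export
stationary_boltzmann <- function(p, sigma_bar, n = 720) {
  if (sigma_bar <= 0) {
    stop("sigma_bar = 0 is degenerate (Dirac masses at the equilibria)")
  }
  th <- density_grid(n)
  u <- energy_bar(th, p)
  orientation_density(exp(-(u - min(u)) / sigma_bar^2), grid = th)
}

#' Stationary state of the control-drift dynamics
#'
#' `f_inf(theta) = C exp( integral_0^theta (theta_hat(s) - s) ds /
#' sigma_bar_c^2 )`, with the cumulative integral evaluated in closed form
#' ([theta_hat_cumint()]).  Its modes are `theta_eq` and `pi - theta_eq`.
#' A user-supplied `theta_hat_map` is integrated by midpoint quadrature
#' instead; if its drift does not integrate to zero over `[0, pi)` the
#' density is not periodic (`f(0) != f(pi)`) and a warning is raised.
#'
#' @param theta_eq Case-1 equilibrium angle in `(0, pi/2)`.
#' @param sigma_bar_c effective control diffusion amplitude (> 0),
#'   `sigma_bar_c^2 = sigma_c^2 / (2 eps^2)`.
#' @param n number of grid cells.
#' @param theta_hat_map optional function `theta -> theta_hat` replacing
#'   the built-in piecewise-quadratic construction.
#' @return an `orientation_density`.
#' @export
stationary_control <- function(theta_eq, sigma_bar_c, n = 720,
                               theta_hat_map = NULL) {
  if (sigma_bar_c <= 0) stop("sigma_bar_c must be positive")
  th <- density_grid(n)
  if (is.null(theta_hat_map)) {
    v <- theta_hat_cumint(th, theta_eq)
  } else {
    # midpoint cumulative integral of (theta_hat - s) on the solver grid
    h <- pi / n
    integrand <- theta_hat_map(th) - th
    tot <- sum(integrand) * h
    if (abs(tot) > 1e-6) {
      warning("theta_hat drift does not integrate to zero over [0, pi); ",
              "stationary density has f(0) != f(pi)")
    }
    v <- cumsum(integrand) * h - integrand * h / 2
  }
  orientation_density(exp((v - max(v)) / sigma_bar_c^2), grid = th)
}

# sparse generator L of the semi-discrete system df/dt = L f
.fp_operator <- function(spec, n) {
  h <- pi / n
  centers <- density_grid(n)
  interfaces <- (0:n) * h
  vc <- spec$potential(centers)
  vi <- spec$potential(interfaces %% pi)
  s2 <- spec$sigma_bar^2
  clamp <- function(x) pmin(pmax(x, -700), 700)
  c2 <- s2 / h^2
  up  <- c(vc[-1], vc[1])                     # V at cell i+1
  dn  <- c(vc[n], vc[-n])                     # V at cell i-1
  ep  <- exp(clamp((up - vi[-1]) / s2))       # coeff f_{i+1} in F_{i+1/2}
  em  <- exp(clamp((vc - vi[-1]) / s2))       # coeff f_i     in F_{i+1/2}
  emm <- exp(clamp((vc - vi[-(n + 1)]) / s2)) # coeff f_i     in F_{i-1/2}
  epm <- exp(clamp((dn - vi[-(n + 1)]) / s2)) # coeff f_{i-1} in F_{i-1/2}
  i <- rep(seq_len(n), 3)
  j <- c(seq_len(n), c(2:n, 1L), c(n, seq_len(n - 1)))
  x <- c(-c2 * (em + emm), c2 * ep, c2 * epm)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' Evolve a density under the Fokker-Planck equation
#'
#' Integrates `df/dt = d/dtheta [ V' f ] + sigma_bar^2 d2f/dtheta2` in the
#' nondimensional time `t_bar = t eps^2 / lambda_theta`, starting from
#' `f0`, with the conservative exponentially fitted finite-volume scheme
#' and backward-Euler time stepping (see file header).  Mass is conserved
#' to solver precision, positivity is preserved, and the analytic
#' stationary state is a fixed point of the discrete scheme.
#'
#' @param f0 initial `orientation_density`.
#' @param spec a [drift_spec()].
#' @param t_end final (nondimensional) time.
#' @param dt time step; defaults to `t_end / 2000`.
#' @param record optional vector of times at which to store snapshots.
#' @return an object of class `fp_solution`: list with the final `density`,
#'   the requested `snapshots` (list of `orientation_density`), their
#'   `times`, and the `spec`.
#' @export
fp_evolve <- function(f0, spec, t_end, dt = NULL, record = NULL) {
  stopifnot(inherits(f0, "orientation_density"), inherits(spec, "drift_spec"),
            t_end > 0)
  if (is.null(dt)) dt <- t_end / 2000
  if (dt <= 0 || dt > t_end) stop("need 0 < dt <= t_end")
  n <- f0$n
  L <- .fp_operator(spec, n)
  A <- Matrix::Diagonal(n) - dt * L
  fac <- Matrix::lu(A)
  n_steps <- ceiling(t_end / dt - 1e-9)
  rec_steps <- if (is.null(record)) integer(0) else {
    pmin(pmax(round(record / dt), 1L), n_steps)
  }
  f <- f0$values
  snapshots <- list()
  times <- numeric(0)
  t <- 0
  for (k in seq_len(n_steps)) {
    step <- min(dt, t_end - t)
    if (abs(step - dt) > 1e-12 * dt) {
      # final partial step: refactorise for the shorter step
      f <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - step * L, f))
    } else {
      f <- as.numeric(Matrix::solve(fac, f))
    }
    t <- t + step
    if (any(!is.finite(f))) {
      stop("Fokker-Planck blow-up at t = ", format(t), " with dt = ",
           format(dt))
    }
    if (k %in% rec_steps) {
      snapshots[[length(snapshots) + 1L]] <-
        orientation_density(f, grid = f0$grid, time = t, normalize = FALSE)
      times <- c(times, t)
    }
  }
  structure(list(density = orientation_density(f, grid = f0$grid, time = t,
                                               normalize = FALSE),
                 snapshots = snapshots, times = times, spec = spec),
            class = "fp_solution")
}

#' @export
print.fp_solution <- function(x, ...) {
  cat(sprintf("Fokker-Planck solution (%s drift, sigma_bar = %.4g) at t = %g\n",
              x$spec$kind, x$spec$sigma_bar, x$density$time))
  print(x$density)
  invisible(x)
}

#' Relative Shannon entropy
#'
#' `H(f, f_inf) = integral f log(f / f_inf) dtheta >= 0`, with the
#' convention `0 log 0 = 0`.  It vanishes iff `f = f_inf` and decreases
#' monotonically along Fokker-Planck trajectories toward the stationary
#' state (numerically verified; the periodic flux makes `f_inf` a global
#' attractor).  If `f` puts mass where `f_inf` vanishes the entropy is
#' `+Inf`.
#'
#' @param f,f_inf normalised `orientation_density` objects on one grid.
#' @return a nonnegative scalar (possibly `Inf`).
#' @export
relative_entropy <- function(f, f_inf) {
  if (f$n != f_inf$n) stop("densities live on different grids")
  fi <- f$values
  gi <- f_inf$values
  bad <- fi > 0 & gi <= 0
  if (any(bad)) return(Inf)
  pos <- fi > 0
  max(sum(fi[pos] * log(fi[pos] / gi[pos])) * f$h, 0)
}
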