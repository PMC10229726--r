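# Particle-level Monte Carlo of the reorientation process.
#
# Three microscopic rules share one ensemble representation:
#   * Euler-Maruyama steps of the overdamped Langevin equation
#       dtheta = -(eps^2/lambda_theta) U'(theta) dt
#                + sqrt(sigma^2/lambda_theta) dW,
#   * the discrete-time kinetic jump process, where over each event-clock
#     step Delta_t a cell reorients with probability Delta_t/lambda_theta
#     and, if it does, applies a rescaled kick (energy or control rule)
#     with rescaling parameter gamma << 1,
#   * the optimal-control kick theta' = theta + gamma eps^2
#     (theta_hat(theta) - theta) + sqrt(gamma sigma_c^2) xi.
# All updates wrap modulo pi.  Randomness comes from R's RNG, so a single
# set.seed() call makes any run bit-for-bit reproducible.

#' Ensemble of orientation angles
#'
#' @param n number of particles (fixed over a run: mass is conserved).
#' @param init `"uniform"` draws angles uniformly on `[0, pi)`; `"delta"`
#'   places all particles at `angle`.
#' @param angle initial angle for `init = "delta"` (radians).
#' @param time initial time stamp.
#' @return an object of class `ensemble` with fields `angles`, `n`, `time`.
#' @export
new_ensemble <- function(n, init = c("uniform", "delta"), angle = NULL,
                         time = 0) {
  init <- match.arg(init)
  angles <- switch(init,
    uniform = stats::runif(n, 0, pi),
    delta = {
      if (is.null(angle)) stop("init = 'delta' needs an angle")
      rep(angle %% pi, n)
    })
  structure(list(angles = angles, n = n, time = time), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  s <- ensemble_stats(x)
  cat(sprintf(
    "Ensemble: %d particles at t = %g; linear mean %.2f deg, sd %.2f deg\n",
    x$n, x$time, s$linear_mean_deg, s$sd_deg))
  invisible(x)
}

#' Energy-minimising reorientation kick
#'
#' `theta' = theta - gamma eps^2 dU/dtheta + sqrt(gamma sigma^2) xi mod pi`:
#' the discrete-time microscopic rule whose quasi-invariant limit
#' (`gamma -> 0`) recovers the energy-drift Fokker-Planck equation.
#'
#' @param theta current angle(s).
#' @param p an [energy_params()] object (provides `eps` and the energy).
#' @param gamma rescaling parameter (> 0, << 1 in the kinetic limit).
#' @param sigma noise amplitude.
#' @param xi standard normal draws (defaults to fresh draws).
#' @return new angles in `[0, pi)`.
#' @export
microscopic_rule_energy <- function(theta, p, gamma, sigma,
                                    xi = stats::rnorm(length(theta))) {
  if (gamma < 0) stop("gamma must be nonnegative")
  (theta - gamma * p$eps^2 * energy_bar_deriv(theta, p) +
     sqrt(gamma * sigma^2) * xi) %% pi
}

#' Optimal-control reorientation kick
#'
#' `theta' = theta + gamma eps^2 (theta_hat(theta) - theta) +
#' sqrt(gamma sigma_c^2) xi mod pi`.  The deterministic part fixes exactly
#' the two oblique equilibria `theta_eq` and `pi - theta_eq`.
#'
#' @param theta current angle(s).
#' @param theta_eq Case-1 equilibrium angle.
#' @param eps strain amplitude.
#' @param gamma rescaling parameter (> 0).
#' @param sigma_c control noise amplitude.
#' @param xi standard normal draws.
#' @return new angles in `[0, pi)`.
#' @export
microscopic_rule_control <- function(theta, theta_eq, eps, gamma, sigma_c,
                                     xi = stats::rnorm(length(theta))) {
  if (gamma < 0) stop("gamma must be nonnegative")
  (theta + gamma * eps^2 * (theta_hat(theta, theta_eq) - theta) +
     sqrt(gamma * sigma_c^2) * xi) %% pi
}

#' Jump-process rule
#'
#' Event clock plus kick: over a step `delta_t` each cell independently
#' reorients with probability `delta_t / lambda_theta` (a Bernoulli event;
#' `delta_t <= lambda_theta` is required for this to be a probability),
#' applying the energy or control kick when it does.
#'
#' @param kind `"energy"` or `"control"`.
#' @param gamma rescaling parameter of the kick.
#' @param sigma noise amplitude (`sigma` for energy, `sigma_c` for control).
#' @param lambda_theta reorientation timescale (s).
#' @param delta_t event-clock step (s); default `lambda_theta / 10`.
#' @return an object of class `jump_rule`.
#' @export
jump_rule <- function(kind = c("energy", "control"), gamma, sigma,
                      lambda_theta, delta_t = lambda_theta / 10) {
  kind <- match.arg(kind)
  if (delta_t > lambda_theta) {
    stop("delta_t must not exceed lambda_theta (event probability > 1)")
  }
  if (delta_t <= 0 || lambda_theta <= 0) stop("timescales must be positive")
  structure(list(kind = kind, gamma = gamma, sigma = sigma,
                 lambda_theta = lambda_theta, delta_t = delta_t),
            class = "jump_rule")
}

#' One step of the kinetic jump process
#'
#' Each particle independently reorients with probability
#' `delta_t / lambda_theta`; reorienting particles apply the rule's kick,
#' all others are unchanged.  The ensemble size is conserved.
#'
#' @param ens an [new_ensemble()] object.
#' @param rule a [jump_rule()].
#' @param p an [energy_params()] object.
#' @param eps strain amplitude used by the kick; defaults to `p$eps`
#'   (a stretch schedule may override it, e.g. 0 after stretch-off).
#' @param theta_eq equilibrium angle for the control kick (computed from
#'   `p` when omitted).
#' @return the updated ensemble (time advanced by `delta_t`).
#' @export
jump_step <- function(ens, rule, p, eps = p$eps, theta_eq = NULL) {
  moving <- stats::runif(ens$n) < rule$delta_t / rule$lambda_theta
  if (any(moving)) {
    th <- ens$angles[moving]
    ens$angles[moving] <- if (rule$kind == "energy") {
      pp <- p
      pp$eps <- eps
      microscopic_rule_energy(th, pp, rule$gamma, rule$sigma)
    } else {
      if (is.null(theta_eq)) theta_eq <- equilibrium_angle(p$alpha, p$r)
      microscopic_rule_control(th, theta_eq, eps, rule$gamma, rule$sigma)
    }
  }
  ens$time <- ens$time + rule$delta_t
  ens
}

#' Run the kinetic jump process
#'
#' Iterates [jump_step()] to `t_end`, optionally under a piecewise strain
#' schedule, recording summary statistics at requested times and (when
#' `accumulate_from` is set) a time-averaged histogram of the post-burn-in
#' states, which sharply reduces Monte Carlo noise in stationary
#' comparisons.
#'
#' @param ens initial ensemble.
#' @param rule a [jump_rule()].
#' @param p an [energy_params()] object.
#' @param t_end final time (s).
#' @param eps_schedule optional function `time -> eps` (e.g. stretch-off).
#' @param record optional times at which to record [ensemble_stats()].
#' @param accumulate_from optional time after which an averaged histogram
#'   (with `n_bins` bins) is accumulated.
#' @param n_bins bins of the accumulated histogram.
#' @return list with the final `ensemble`, a `series` data frame of
#'   recorded statistics, and `density` (time-averaged
#'   `orientation_density`, or `NULL`).
#' @export
simulate_jump <- function(ens, rule, p, t_end, eps_schedule = NULL,
                          record = NULL, accumulate_from = NULL,
                          n_bins = 90) {
  theta_eq <- if (rule$kind == "control") {
    equilibrium_angle(p$alpha, p$r)
  } else {
    NULL
  }
  n_steps <- ceiling((t_end - ens$time) / rule$delta_t - 1e-9)
  rec_steps <- if (is.null(record)) integer(0) else {
    pmax(round((record - ens$time) / rule$delta_t), 1L)
  }
  counts <- rep(0, n_bins)
  n_acc <- 0L
  series <- list()
  for (k in seq_len(n_steps)) {
    eps_k <- if (is.null(eps_schedule)) p$eps else eps_schedule(ens$time)
    ens <- jump_step(ens, rule, p, eps = eps_k, theta_eq = theta_eq)
    if (!is.null(accumulate_from) && ens$time >= accumulate_from) {
      idx <- pmin(floor(ens$angles / pi * n_bins) + 1L, n_bins)
      counts <- counts + tabulate(idx, nbins = n_bins)
      n_acc <- n_acc + 1L
    }
    if (k %in% rec_steps) {
      series[[length(series) + 1L]] <-
        c(time = ens$time, unlist(ensemble_stats(ens)))
    }
  }
  density <- if (n_acc > 0L) {
    orientation_density(counts / (sum(counts) * pi / n_bins),
                        grid = density_grid(n_bins), time = ens$time,
                        normalize = FALSE)
  } else {
    NULL
  }
  list(ensemble = ens,
       series = if (length(series)) {
         as.data.frame(do.call(rbind, series))
       } else {
         NULL
       },
       density = density)
}

#' Euler-Maruyama integration of the Langevin reorientation SDE
#'
#' Each particle follows
#' `theta <- theta - (eps(t)^2 / lambda_theta) U'(theta) dt +
#' sqrt(sigma^2 dt / lambda_theta) xi`, wrapped modulo pi.  `lambda_theta`,
#' `dt` and `t_end` must share one time unit; the dynamics depend on them
#' only through `dt / lambda_theta` and `t / lambda_theta`.
#'
#' @param ens initial ensemble.
#' @param p an [energy_params()] object.
#' @param sigma noise amplitude.
#' @param lambda_theta reorientation timescale.
#' @param dt time step (same unit as `lambda_theta`).
#' @param t_end final time.
#' @param eps_schedule optional function `time -> eps` overriding `p$eps`
#'   (piecewise-constant stretch schedules).
#' @param record optional times at which to record [ensemble_stats()].
#' @return list with the final `ensemble` and a `series` data frame.
#' @export
euler_maruyama <- function(ens, p, sigma, lambda_theta, dt, t_end,
                           eps_schedule = NULL, record = NULL) {
  stopifnot(dt > 0, lambda_theta > 0, t_end > ens$time)
  n_steps <- ceiling((t_end - ens$time) / dt - 1e-9)
  rec_steps <- if (is.null(record)) integer(0) else {
    pmax(round((record - ens$time) / dt), 1L)
  }
  noise_sd <- sqrt(sigma^2 / lambda_theta)
  series <- list()
  for (k in seq_len(n_steps)) {
    step <- min(dt, t_end - ens$time)
    eps_k <- if (is.null(eps_schedule)) p$eps else eps_schedule(ens$time)
    drift <- -(eps_k^2 / lambda_theta) *
      energy_bar_deriv(ens$angles, p) * step
    if (max(abs(drift)) > pi / 2) {
      stop("time step too large: |drift * dt| exceeds pi/2 (dt = ",
           format(dt), ")")
    }
    ens$angles <- (ens$angles + drift +
                     noise_sd * sqrt(step) * stats::rnorm(ens$n)) %% pi
    ens$time <- ens$time + step
    if (k %in% rec_steps) {
      series[[length(series) + 1L]] <-
        c(time = ens$time, unlist(ensemble_stats(ens)))
    }
  }
  list(ensemble = ens,
       series = if (length(series)) {
         as.data.frame(do.call(rbind, series))
       } else {
         NULL
       })
}

#' Histogram density of an ensemble
#'
#' Bins the angles into `n_bins` equal bins and normalises to a density.
#' `fold = TRUE` maps `theta -> pi - theta` for `theta > pi/2` before
#' binning (the first-quadrant representation used by experimentalists);
#' `restrict = TRUE` instead discards particles above `pi/2` and
#' renormalises.  For symmetric ensembles the two agree in expectation.
#'
#' @param ens an ensemble.
#' @param n_bins number of bins (>= 2).
#' @param fold fold onto `[0, pi/2)` before binning.
#' @param restrict restrict to `[0, pi/2)` and renormalise.
#' @return an `orientation_density` on `[0, pi)` (or on `[0, pi/2)` when
#'   folded/restricted, with grid spanning that half interval).
#' @export
ensemble_to_density <- function(ens, n_bins = 90, fold = FALSE,
                                restrict = FALSE) {
  if (ens$n == 0L) stop("empty ensemble")
  if (n_bins < 2L) stop("need n_bins >= 2")
  th <- ens$angles
  upper <- pi
  if (fold && restrict) stop("choose one of fold or restrict")
  if (fold) {
    th <- ifelse(th > pi / 2, pi - th, th)
    upper <- pi / 2
  }
  if (restrict) {
    th <- th[th < pi / 2]
    if (!length(th)) stop("no particles below pi/2")
    upper <- pi / 2
  }
  idx <- pmin(floor(th / upper * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  h <- upper / n_bins
  grid <- (seq_len(n_bins) - 0.5) * h
  vals <- counts / (length(th) * h)
  structure(list(grid = grid, values = vals, n = n_bins, h = h,
                 time = ens$time),
            class = "orientation_density")
}

#' Summary statistics of an ensemble
#'
#' First-quadrant statistics computed directly from the particles after
#' folding `theta -> pi - theta`: linear mean, standard deviation,
#' circular mean (arctangent of the folded trigonometric moments) and the
#' fraction of particles in an angular window.
#'
#' @param ens an ensemble.
#' @param window optional 2-vector (degrees) for the reported fraction.
#' @return a list with `linear_mean_deg`, `circular_mean_deg`, `sd_deg`
#'   and (if `window` is given) `fraction_in_window`.
#' @export
ensemble_stats <- function(ens, window = NULL) {
  folded <- ifelse(ens$angles > pi / 2, pi - ens$angles, ens$angles)
  lm <- mean(folded)
  cm <- atan2(mean(sin(folded)), mean(cos(folded)))
  out <- list(linear_mean_deg = to_degrees(lm),
              circular_mean_deg = to_degrees(cm),
              sd_deg = to_degrees(stats::sd(folded)))
  if (!is.null(window)) {
    w <- to_radians(window)
    out$fraction_in_window <- mean(folded >= w[1] & folded <= w[2])
  }
  out
}
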