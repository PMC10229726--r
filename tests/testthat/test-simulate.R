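# Monte Carlo engines: Euler-Maruyama SDE, kinetic jump process, kicks.

test_that("microscopic kicks have the printed fixed points and moments", {
  p <- hayakawa_params()
  te <- equilibrium_angle(p$alpha, p$r)
  # zero noise at an equilibrium: stay put
  expect_equal(microscopic_rule_energy(te, p, gamma = 0.05, sigma = 0.1,
                                       xi = 0), te)
  expect_equal(microscopic_rule_control(te, te, p$eps, gamma = 0.05,
                                        sigma_c = 0.1, xi = 0), te)
  # gamma = 0 is the identity whatever the draw
  set.seed(5)
  th <- runif(50, 0, pi)
  expect_equal(microscopic_rule_energy(th, p, 0, 0.3), th)
  # control kick from theta = 0 moves toward pi/2 by gamma*eps^2*pi/2
  g <- 0.01
  expect_equal(microscopic_rule_control(0, te, p$eps, g, 0.5, xi = 0),
               g * p$eps^2 * pi / 2)
  # moment oracle: mean displacement = -gamma eps^2 U'(theta)
  set.seed(11)
  ndraw <- 1e5
  th0 <- 0.9
  g <- 0.01
  sg <- 0.3
  disp <- microscopic_rule_energy(rep(th0, ndraw), p, g, sg) - th0
  disp <- ifelse(disp > pi / 2, disp - pi, ifelse(disp < -pi / 2,
                                                  disp + pi, disp))
  expect_equal(mean(disp), -g * p$eps^2 * energy_bar_deriv(th0, p),
               tolerance = 3 * sqrt(g * sg^2 / ndraw) /
                 abs(g * p$eps^2 * energy_bar_deriv(th0, p)))
})

test_that("jump_step reorients a binomial fraction and conserves particles",
{
  p <- hayakawa_params()
  rule_all <- jump_rule("energy", gamma = 0.05, sigma = 0.2,
                        lambda_theta = 1, delta_t = 1)
  set.seed(21)
  ens <- new_ensemble(2000)
  before <- ens$angles
  ens2 <- jump_step(ens, rule_all, p)
  expect_equal(ens2$n, 2000L)
  # delta_t / lambda_theta = 1: every particle reoriented (noise nonzero)
  expect_true(all(ens2$angles != before))
  expect_true(all(ens2$angles >= 0 & ens2$angles < pi))
  # delta_t / lambda_theta = 0.25: binomial fraction
  rule_q <- jump_rule("energy", gamma = 0.05, sigma = 0.2,
                      lambda_theta = 1, delta_t = 0.25)
  set.seed(22)
  n_big <- 1e5
  ens <- new_ensemble(n_big)
  before <- ens$angles
  moved <- mean(jump_step(ens, rule_q, p)$angles != before)
  expect_lt(abs(moved - 0.25), 3 * sqrt(0.25 * 0.75 / n_big))
  expect_error(jump_rule("energy", 0.05, 0.2, lambda_theta = 1,
                         delta_t = 2), "exceed")
})

test_that("euler_maruyama fixes noiseless equilibria, wraps angles, and is
           deterministic under a seed", {
  p <- hayakawa_params()
  te <- equilibrium_angle(p$alpha, p$r)
  ens <- new_ensemble(1, "delta", angle = te)
  run <- euler_maruyama(ens, p, sigma = 0, lambda_theta = 0.18, dt = 0.06,
                        t_end = 3)
  expect_equal(run$ensemble$angles, te, tolerance = 1e-12)
  set.seed(33)
  e1 <- euler_maruyama(new_ensemble(500), p, 0.04, 0.18, 0.06, 1)
  set.seed(33)
  e2 <- euler_maruyama(new_ensemble(500), p, 0.04, 0.18, 0.06, 1)
  expect_identical(e1$ensemble$angles, e2$ensemble$angles)
  expect_true(all(e1$ensemble$angles >= 0 & e1$ensemble$angles < pi))
  # oversized drift step is refused
  expect_error(euler_maruyama(new_ensemble(100), p, 0.04, 1e-4, 10, 20),
               "time step too large")
})

test_that("SDE histograms agree with the Fokker-Planck solver (weak
           convergence) at matched checkpoints", {
  p <- hayakawa_params()
  sb <- effective_sigma(0.04, 0.2)
  spec <- drift_spec("energy", sb, p = p)
  set.seed(44)
  nmc <- 4e4
  ens <- new_ensemble(nmc)
  # lambda_theta = 0.18, dt = 0.06 in the hour unit: t_bar = t eps^2/0.18
  for (t_hr in c(1, 3)) {
    run <- euler_maruyama(ens, p, 0.04, 0.18, 0.06, t_hr)
    sol <- fp_evolve(uniform_density(720), spec,
                     t_end = nondimensional_time(run$ensemble$time,
                                                 p$eps, 0.18),
                     dt = 5e-4)
    hist30 <- ensemble_to_density(run$ensemble, n_bins = 30)
    fp30 <- orientation_density(
      colMeans(matrix(sol$density$values, nrow = 24)),
      grid = density_grid(30))
    expect_lt(l1_distance(hist30, fp30), 3 * sqrt(30 / nmc))
    ens <- run$ensemble   # continue the same trajectory to the next time
  }
})

test_that("energy-rule jump process converges to the Boltzmann state as
           gamma decreases (quasi-invariant limit)", {
  # numerics-scale parameters (eps = 1, sigma = 1 -> sigma_bar^2 = 0.5)
  # keep run lengths short while making the O(gamma) bias dominate noise
  p <- energy_params(r = 0.4, eps = 1, k_s = KS_FIX, alpha = ALPHA_FIX)
  fi <- stationary_boltzmann(p, sqrt(0.5), n = 60)
  set.seed(42)
  d <- vapply(c(0.1, 0.03, 0.01), function(g) {
    rule <- jump_rule("energy", gamma = g, sigma = 1, lambda_theta = 1,
                      delta_t = 0.5)
    nst <- round(8 / g)
    run <- simulate_jump(new_ensemble(5e4), rule, p, t_end = nst * 0.5,
                         accumulate_from = nst * 0.25 * 0.5, n_bins = 60)
    l1_distance(run$density, fi)
  }, numeric(1))
  expect_true(all(diff(d) < 0))
  expect_lt(d[3], 0.05)
})

test_that("control-rule jump process reaches the control stationary state", {
  # alignment-capable noise scale; gamma = 1e-2 as in the published runs
  p <- energy_params(r = 0.15, eps = 1, k_s = KS_FIX, alpha = ALPHA_FIX)
  te <- equilibrium_angle(p$alpha, p$r)
  sbc <- sqrt(0.3)
  fi <- stationary_control(te, sbc, n = 45)
  set.seed(7)
  rule <- jump_rule("control", gamma = 1e-2, sigma = sbc * sqrt(2) * p$eps,
                    lambda_theta = 1, delta_t = 0.5)
  nst <- 1200
  run <- simulate_jump(new_ensemble(4e4), rule, p, t_end = nst * 0.5,
                       accumulate_from = nst * 0.5 * 0.5, n_bins = 45)
  expect_lt(l1_distance(run$density, fi), 0.05)
  # modes at theta_eq and pi - theta_eq within one histogram cell
  first <- run$density$grid < pi / 2
  m1 <- run$density$grid[first][which.max(run$density$values[first])]
  m2 <- run$density$grid[!first][which.max(run$density$values[!first])]
  expect_lt(abs(m1 - te), pi / 45 + 1e-12)
  expect_lt(abs(m2 - (pi - te)), pi / 45 + 1e-12)
})

test_that("ensemble_to_density matches a binomial oracle and folding agrees
           with restriction for symmetric ensembles", {
  set.seed(55)
  n <- 2e5
  ens <- new_ensemble(n)
  d18 <- ensemble_to_density(ens, n_bins = 18)   # 10-degree bins
  expect_equal(integrate_density(d18), 1, tolerance = 1e-12)
  freq <- d18$values * d18$h
  # 3.5 sigma per bin: Bonferroni-safe for the 18 simultaneous bins
  expect_true(all(abs(freq - 1 / 18) <
                    3.5 * sqrt((1 / 18) * (17 / 18) / n)))
  fold <- ensemble_to_density(ens, n_bins = 9, fold = TRUE)
  restr <- ensemble_to_density(ens, n_bins = 9, restrict = TRUE)
  expect_lt(sum(abs(fold$values - restr$values)) * fold$h,
            4 * sqrt(9 / n))
  expect_error(ensemble_to_density(new_ensemble(10), fold = TRUE,
                                   restrict = TRUE), "choose one")
  expect_error(ensemble_to_density(structure(list(angles = numeric(0),
                                                  n = 0L, time = 0),
                                             class = "ensemble")),
               "empty")
})
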