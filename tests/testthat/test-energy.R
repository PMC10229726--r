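# Orthotropic energy, its derivative, and the bifurcation-case geometry.

test_that("energy_bar reproduces hand-computed values and the U1 symmetry", {
  p <- energy_params(r = 0, eps = 0.1, k_s = 0.7, k_perp = 0.2754)
  # theta = pi/4: cos 2theta = 0, so U = (1 + k_perp + k_s) / 2
  expect_equal(energy_bar(pi / 4, p), 0.5 * (1 + 0.2754 + 0.7),
               tolerance = 1e-12)
  for (p in random_stiffness_params(5)) {
    th <- runif(20, -2 * pi, 2 * pi)
    expect_equal(energy_bar(th, p), energy_bar(pi - th, p), tolerance = 1e-12)
    expect_equal(energy_bar(th, p), energy_bar(pi + th, p), tolerance = 1e-12)
    expect_equal(energy_bar(th, p), energy_bar(2 * pi - th, p),
                 tolerance = 1e-12)
  }
})

test_that("energy_bar_deriv matches a finite-difference oracle and vanishes
           at stationary points", {
  for (p in random_stiffness_params(4, seed = 77)) {
    th <- runif(100, 0, pi)
    hfd <- 1e-6
    fd <- (energy_bar(th + hfd, p) - energy_bar(th - hfd, p)) / (2 * hfd)
    expect_equal(energy_bar_deriv(th, p), fd, tolerance = 1e-6)
    expect_equal(energy_bar_deriv(c(0, pi / 2, pi), p), c(0, 0, 0))
  }
  # Case-1 equilibrium is a stationary point and a strict local minimum
  p <- hayakawa_params()
  te <- equilibrium_angle(p$alpha, p$r)
  expect_equal(energy_bar_deriv(te, p), 0, tolerance = 1e-12)
  hh <- 1e-4
  curv <- (energy_bar(te + hh, p) - 2 * energy_bar(te, p) +
             energy_bar(te - hh, p)) / hh^2
  expect_gt(curv, 0)
  # brute-force grid minimisation agrees with the closed form
  grid <- seq(0, pi / 2, length.out = 20001)
  expect_lt(abs(grid[which.min(energy_bar(grid, p))] - te), 1e-4)
})

test_that("alpha/k_perp conversions are exact inverses with the printed values", {
  expect_equal(alpha_from_stiffness(0, 1), 0)
  expect_equal(alpha_from_stiffness(0.5, 0.5), 2)
  expect_equal(k_perp_from_alpha(0.7, 0.794), 0.494 / 1.794, tolerance = 1e-12)
  expect_equal(alpha_from_stiffness(k_perp_from_alpha(0.7, 0.794), 0.7),
               0.794, tolerance = 1e-12)
  # round trip alpha -> k_perp -> alpha across random draws
  set.seed(3)
  for (k in 1:20) {
    a <- runif(1, -0.9, 3)
    ks <- runif(1, max(0, 1 - a) + 0.01, 3)
    expect_equal(alpha_from_stiffness(k_perp_from_alpha(ks, a), ks), a,
                 tolerance = 1e-12)
  }
  expect_error(alpha_from_stiffness(1, 0.5), "singular")
  expect_error(k_perp_from_alpha(1 - 0.794, 0.794), "compatibility")
})

test_that("rho(alpha) and its reciprocal behave as printed", {
  expect_equal(rho_alpha(0), 1)
  expect_equal(bifurcation_r(0.794), (1 - 0.794) / (1 + 0.794))
  expect_equal(round(bifurcation_r(0.794), 3), 0.115)
  a <- seq(-0.95, 0.95, by = 0.1)
  expect_equal(rho_alpha(a) * rho_alpha(-a), rep(1, length(a)),
               tolerance = 1e-12)
  expect_error(rho_alpha(1), "singular")
})

test_that("classify_case partitions (alpha, r) and returns true equilibria", {
  expect_identical(classify_case(0.794, 0.4)$case_id, 1L)
  expect_identical(classify_case(0.794, 0)$case_id, 3L)
  expect_equal(classify_case(0.794, 0)$equilibria, c(pi / 2, 3 * pi / 2))
  expect_identical(classify_case(2, 0.01)$case_id, 1L)
  expect_identical(classify_case(2, 5)$case_id, 1L)
  expect_identical(classify_case(-2, 0.5)$case_id, 2L)
  expect_identical(classify_case(-0.5, 1)$case_id, 2L)
  expect_identical(classify_case(-0.5, 0.1)$case_id, 3L)
  expect_identical(classify_case(-0.5, 10)$case_id, 4L)
  expect_identical(classify_case(0.794, 10)$case_id, 4L)
  # closed-interval boundary goes to Case 1 (ties toward the first case)
  expect_identical(classify_case(0.794, bifurcation_r(0.794))$case_id, 1L)
  # exactly one case for random inputs; equilibria are stationary points
  set.seed(9)
  for (k in 1:40) {
    a <- runif(1, -2, 2)
    r <- runif(1, 0, 4)
    cl <- classify_case(a, r)
    expect_true(cl$case_id %in% 1:4)
    expect_length(cl$equilibria, if (cl$case_id %in% 1:2) 4L else 2L)
    lo <- max(0, 1 - a) + 0.05
    if (lo >= 2) next       # no admissible k_s for strongly negative alpha
    ks <- runif(1, lo, 2)
    kp <- tryCatch(k_perp_from_alpha(ks, a), error = function(e) NULL)
    if (!is.null(kp) && kp > 0 && kp != 1) {
      p <- energy_params(r = r, eps = 0.1, k_s = ks, k_perp = kp)
      expect_lt(max(abs(energy_bar_deriv(cl$equilibria, p))), 1e-10)
    }
  }
})

test_that("equilibrium_angle matches Eq-of-motion geometry and is continuous
           through r = 1", {
  expect_equal(equilibrium_angle(0.794, 1), pi / 4)
  expect_equal(round(to_degrees(equilibrium_angle(0.794, 0.4))), 61)
  expect_equal(round(to_degrees(equilibrium_angle(0.794, 0.15))), 79)
  expect_error(equilibrium_angle(0.794, 0.01), "not Case 1")
  # continuity of theta_eq as r -> 1 from either side
  eps_r <- c(1e-3, 1e-6)
  for (d in eps_r) {
    expect_lt(abs(equilibrium_angle(0.794, 1 - d) - pi / 4), 2 * d)
    expect_lt(abs(equilibrium_angle(0.794, 1 + d) - pi / 4), 2 * d)
  }
})

test_that("energy_params constructors validate and cache consistently", {
  p1 <- energy_params(r = 0.4, eps = 0.2, k_s = 0.7, alpha = 0.794)
  p2 <- energy_params(r = 0.4, eps = 0.2, k_s = 0.7, k_perp = p1$k_perp)
  expect_equal(p2$alpha, 0.794, tolerance = 1e-12)
  expect_error(energy_params(r = 0.4, eps = 0.2, k_s = 0.2, alpha = 0.794),
               "compatibility")
  expect_error(energy_params(r = 0.4, eps = 0.2, k_s = 0.7), "k_perp or alpha")
  expect_error(energy_params(r = 0.4, eps = 0.2, k_s = 0.7, k_perp = 0.5,
                             alpha = 0.9), "inconsistent")
})
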