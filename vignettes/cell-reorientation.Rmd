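---
title: "Modelling cell reorientation under cyclic stretch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell reorientation under cyclic stretch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellreorient)
```

## The model

Cells seeded on a cyclically stretched elastic substratum develop stress
fibers anchored by focal adhesions and reorient relative to the main
stretch direction.  Because a cell has no head or tail, orientations
`theta` and `theta + pi` are identical, and the choice of axes makes
`theta` and `pi - theta` energetically equivalent; every density in this
package therefore lives on the periodic interval `[0, pi)` and inherits
the mirror symmetry `f(pi - theta) = f(theta)` (called F4 below) whenever
the initial condition has it.

The elastic state of a cell oriented at `theta` under the plane strain
`E = diag(eps, -r*eps)` is summarised by the dimensionless orthotropic
energy

`U(theta) = 1/2 { [(r+1)c + 1 - r]^2 + k_perp [(r+1)c - 1 + r]^2 +
k_s (r+1)^2 (1 - c^2) }`,   `c = cos 2theta`,

with stiffness ratios `k_perp`, `k_s` relative to the parallel modulus
(normalised to one; the dimensional prefactor enters the dynamics only
through `eps^2`).  Mixed orthotropic terms are neglected.  The landscape
is classified by `alpha = (1 + k_perp - k_s)/(1 - k_perp)` and `r`
(`classify_case()`): for `alpha` in `(0, 1)` the oblique minima
`theta_eq = 1/2 arccos[(1/alpha)(r-1)/(r+1)]` exist for `r` between
`(1-alpha)/(1+alpha)` and its reciprocal (Case 1, the closed interval;
boundaries resolve to Case 1), degenerating to perpendicular (Case 3) or
parallel (Case 4) alignment outside, with the four-minima Case 2 arising
for negative `alpha`.  The experimentally fitted value `alpha = 0.794` is
used throughout the presets, with `k_s = 0.7` (whose value barely affects
the distributions) and `k_perp` derived as
`(k_s - 1 + alpha)/(1 + alpha)`; positivity of `k_perp` requires
`k_s > 1 - alpha`, which the constructor enforces.

Three stochastic microscopic processes share this landscape:

1. **Langevin SDE** (`euler_maruyama()`):
   `dtheta = -(eps^2/lambda_theta) U'(theta) dt +
   sqrt(sigma^2/lambda_theta) dW`, wrapped modulo pi.  `lambda_theta` is
   the reorientation timescale, `sigma` the noise amplitude.
2. **Kinetic jump process** (`simulate_jump()`): over a clock step
   `Delta_t <= lambda_theta` each cell independently reorients with
   probability `Delta_t/lambda_theta`; a reorienting cell applies the
   rescaled kick `theta' = theta - gamma eps^2 U'(theta) +
   sqrt(gamma sigma^2) xi` (mod pi).  In the quasi-invariant limit
   `gamma -> 0` the induced Boltzmann-type equation converges to the same
   Fokker–Planck equation as the SDE; the package verifies this
   numerically rather than re-deriving it.
3. **Optimal-control rule**: the kick becomes `theta' = theta +
   gamma eps^2 (theta_hat(theta) - theta) + sqrt(gamma sigma_c^2) xi`,
   where `theta_hat` interpolates the two oblique equilibria through a
   weight `p(theta)` (below).  This expresses reorientation as the
   minimiser of a quadratic rotation cost plus an alignment payoff.

The induced Fokker–Planck equations, in the nondimensional time
`t_bar = t eps^2 / lambda_theta`, are drift–diffusion equations on
`[0, pi)` with effective diffusion `sigma_bar^2 = sigma^2/(2 eps^2)` in
the high-frequency regime `lambda*omega >> 1` and
`sigma^2/(2 lambda omega eps^2)` in the low-frequency regime (`lambda` =
viscoelastic relaxation time, `omega` = stretch frequency); the full
oscillation `eps(t) = eps(1 - cos omega t)` is never resolved, only the
mean strain per period, following the quasi-static treatment customary
for these models.  Their stationary states are Boltzmann-like:

* energy drift: `f_inf ∝ exp(-U/sigma_bar^2)` (`stationary_boltzmann()`),
* control drift: `f_inf ∝ exp(∫_0^theta (theta_hat - s) ds /
  sigma_bar_c^2)` (`stationary_control()`), with modes exactly at
  `theta_eq` and `pi - theta_eq`.

`relative_entropy()` implements the Lyapunov functional
`H(f, f_inf) = ∫ f log(f/f_inf)`; its monotone decay along solver
trajectories is asserted in the tests.

## The control target `theta_hat`

The weight `p(theta)` must satisfy seven conditions —
`p(theta_eq) = 1`, `p(pi - theta_eq) = 0`, `p(0) = p(pi/2) = p(pi) = 1/2`
and `p'(theta_eq) = p'(pi - theta_eq) = 0` — so that a cell at an
equilibrium stays, and a cell at a symmetry point is equally likely to
head either way.  A single quadratic cannot satisfy all seven, so the
package uses the minimal-degree construction honouring them: a 4-piece
quadratic spline on `[0, theta_eq]`, `[theta_eq, pi/2]`,
`[pi/2, pi - theta_eq]`, `[pi - theta_eq, pi)`, each piece pinned by its
three endpoint/derivative conditions, C1 at the equilibria and C0 at the
symmetry points.  The construction has the mirror antisymmetry
`p(pi - theta) = 1 - p(theta)`, hence `theta_hat(s) - s` integrates to
zero over `[0, pi)` and the control stationary density is periodic.  The
cumulative drift integral is evaluated in closed form
(`theta_hat_cumint()`), so the stationary state involves no quadrature
error beyond normalisation.

## Numerical choices

* **Spatial scheme.** Conservative finite volumes on a cell-centered
  uniform grid (default 720 cells, quarter-degree resolution — enough to
  resolve the sharpest preset, `sigma_bar^2 = 0.02`), with exponentially
  fitted (Chang–Cooper-type) interface coefficients
  `F_{i+1/2} ∝ f_{i+1} e^{(V_{i+1} - V_{i+1/2})/sb^2} -
  f_i e^{(V_i - V_{i+1/2})/sb^2}`.  The exponents involve only *local*
  potential differences, so no overflow guard is ever active in
  practice; the interface exponentials telescope, making the analytic
  Boltzmann form the exact discrete fixed point.  Columns of the
  generator sum to zero (exact mass conservation) and the implicit
  update matrix is an M-matrix (positivity).
* **Time stepping.** Backward Euler with a reused sparse LU
  factorisation (`Matrix`), default `dt = t_end/2000`; unconditional
  stability covers the stiff small-noise presets.  No scheme is
  prescribed by the modelling literature this follows (which integrates
  by Monte Carlo); the choice is the implementer's.
* **Quadrature.** Composite midpoint everywhere, consistent with the
  finite-volume discretisation; quadrant integrals weight a cell
  straddling `pi/2` by the covered fraction (with the default even cell
  counts the boundary falls on an interface and no partial cell occurs).
* **Calibration.** `calibrate_sigma()` scans 60 log-spaced `sigma_bar`
  values in `[1e-3, 10]`, brackets sign changes of (mean − target) and
  bisects each; the mean-vs-noise curve runs from `theta_eq` at zero
  noise through a single maximum to 45° (uniform), so at most two roots
  exist; both are returned with stationary peak heights, since binned
  histogram height is the natural experimental tie-break.  The
  equibiaxial case `r = 1` has an identically 45° mean ("flat branch")
  and is flagged rather than root-found.
* **Angles and units.** Radians internally, degrees at every I/O
  boundary.  Monte Carlo engines work in physical time; only the ratios
  `t/lambda_theta` and `dt/lambda_theta` (and `eps^2`) enter, so
  `lambda_theta`, `dt`, `t_end` must simply share one unit.  The jump
  engines default to `Delta_t = lambda_theta/10`; property tests use
  `lambda_theta/2` to shorten runs (only the ratio matters).
* **RNG.** All draws come from R's generator: a single `set.seed()`
  makes any run bit-for-bit reproducible, and every scenario report
  records its seed.

## The stated experimental worlds, and two inconsistencies

The scenario presets store published parameter bundles verbatim:
oblique-alignment dynamics (`hayakawa`: `eps = 0.2`, `r = 0.4`,
`sigma = 0.04`), perpendicular-alignment stationary grids (`mao_grid`:
`r = 0`, amplitudes 2/5/10%, 1 Hz vs 0.001 Hz with `lambda = 100` s),
noise-calibrated stationary fits (`faust_a1..a4`: `r = 0.15`, amplitudes
4.9/8.4/11.8/14%), and two control-rule runs (`livne`: `eps = 0.1`,
`lambda_theta = 6.6` s, `sigma_c = 0.7`; `jungbauer`: `eps = 0.08`,
`r = 0.194`, `sigma_c = 1.6`, stretch off after 3000 s).  Two aspects of
those bundles deserve comment, because the package resolves them by
explicit design decisions:

* **Hour-scale Langevin timing.** The oblique-alignment transient is
  reported on an hour scale (means ≈ 54.6° at 1 h and ≈ 62.04° at 3 h
  against a stationary 62.2°), yet the quoted `lambda_theta ≈ 0.18` is
  labelled in seconds.  With seconds, the nondimensional time at 1 h is
  800 and the distribution would be stationary within a minute — both
  checkpoints would read 62.2°.  The dynamics depend only on
  `t/lambda_theta`, and the printed transient is reproduced precisely
  when `lambda_theta = 0.18` and `dt = 0.06` are read in the *same unit
  as the checkpoints* (hours): the preset does so.  The package then
  computes 53.9–54.0° at 1 h, 61.2–61.3° at 3 h and ≈ 92% of cells in
  50–80° at 3 h.  The published triple (62.04°, 85%) is internally
  inconsistent with the model itself: at the time the mean reaches
  62.04° the model's 50–80° fraction is ≈ 98% for `sigma = 0.04`
  (stationary 99.4%), and no `sigma` on either branch of the calibration
  curve attains (62.2°, 85%) at stationarity — the second root,
  `sigma ≈ 0.16`, gives 61% and is excluded by the histogram-height
  tie-break.  The corresponding acceptance test therefore asserts the
  published values, fails honestly, and this paragraph is its analysis;
  nothing was tuned toward the printed numbers.
* **Control noise amplitudes.** With the control diffusion
  `sigma_bar_c^2 = sigma_c^2/(2 eps^2)` and fractional strains, the
  quoted `sigma_c` values give `sigma_bar_c^2` of 24.5 (`livne`) and 200
  (`jungbauer`) against a control-potential depth of order one: the
  stationary state is then essentially uniform and no visible alignment
  develops.  Since the control-run comparisons are qualitative
  (mean-vs-time curves with no printed values), the presets keep the
  quoted numbers, and the control machinery is validated quantitatively
  at alignment-capable noise (`sigma_bar_c^2` ≈ 0.1–0.5) in the property
  tests.  The biaxiality of the `livne` set-up is likewise not quoted;
  the preset uses `r = 0.46` as a package choice, and no numerical
  claim depends on it.

A related scale fact: the exponential relaxation time of the quadrant
mean under the control drift equals `lambda_theta/eps^2` only in the
weak-noise limit.  The tail-fitted constant is `0.87 lambda_theta/eps^2`
at `sigma_bar_c^2 = 0.1` (tested against the 20% band there), but drops
to ≈ 0.5 at 0.3 and ≈ 0.2 at 1.0, because diffusion shortens the
relaxation of the *mean* even though it does not move the modes.

## What the synthetic world does and does not establish

There is no external data: every input is a parameter bundle, and the
"experiments" the tests replicate are the model's own stated worlds
(uniform initial ensembles, mean strain per period, piecewise-constant
stretch schedules).  A green test therefore establishes internal
consistency — Monte Carlo engines, Fokker–Planck solver and closed-form
stationary states agree with each other at the stated tolerances, and
the circular-statistics layer reproduces closed forms — not that the
model fits any particular cell type.  Features of real data deliberately
not emulated: within-period strain oscillation, cell–cell interactions
and contact guidance, spatial heterogeneity of the strain field,
cell-cycle effects on stress-fiber turnover, and measurement error in
orientation extraction.  Monte Carlo tolerances scale as `1/sqrt(N)`;
tests run at `N = 5e3`–`2e5` (desk scale) rather than the published
`1e6`, with tolerances widened accordingly and seeds fixed a priori.

## Known limitations

* Quadrant statistics are meaningful for the oblique and perpendicular
  scenarios (Cases 1 and 3); for Case 4 the interval `(-pi/2, pi/2]`
  would be the informative choice, and the functions compute but do not
  validate that case against any published number.
* The energy-drift Euler–Maruyama engine has the usual O(dt) weak bias;
  at the preset step (`dt/lambda_theta = 1/3`) this is ≈ 0.1° on the
  transient means, below every tolerance used.
* Inertial (second-order) dynamics, escape-rate (Kramers) analysis, the
  full viscoelastic constitutive model (only its diffusion rescaling
  survives here) and the 3D two-angle extension are out of scope.
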