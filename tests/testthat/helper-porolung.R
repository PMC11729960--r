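# Shared fixtures, built in code. Small problem sizes keep the default run
# fast; the heavier calibration checks live in test-acceptance.R.

# A stiffening material set whose recoil is monotone in the working range,
# so an inflation equilibrium exists and limit oracles are well defined.
test_theta <- function() {
  stats::setNames(c(2.8, 9, 0.3, 2, 1.5, 1.2, 5, 1.5, 1, 0.5),
                  parameter_names())
}

test_materials <- function(heterogeneity_sigma = 0.3) {
  theta_to_materials(test_theta(), heterogeneity_sigma = heterogeneity_sigma)
}

small_geometry <- function() {
  lung_geometry(V_total_mL = 600, m_lung_g = 200, rho_lung_g_cm3 = 1.0)
}

# Fast forward run: few patches, short grid.
quick_sim <- function(mats = test_materials(), geom = small_geometry(),
                      n_patches = 3L, seed = 5L, ramp = make_ramp(),
                      n_steps = 60L, ...) {
  lobes <- build_lobes(geom, mats, n_patches = n_patches, seed = seed)
  simulate_inflation(lobes, mats, ramp, n_steps = n_steps, ...)
}

# Independent equilibrium PV oracle: per homogeneous patch, invert
# p = recoil(lam) by bisection and sum the compartment volumes. Written
# against the closed-form recoil terms directly (no ODE, no package
# internals beyond the material constants).
equilibrium_pv_oracle <- function(theta, geom, pressures, n_patches = 1L) {
  mu <- theta[["mu"]]; a <- theta[["alpha"]]
  beta <- theta[["nu"]] / (1 - 2 * theta[["nu"]])
  C10 <- theta[["C10"]]
  cb <- pleura_baseline_default()$coefficients * theta[["lambda"]]
  t0 <- 0.06; af <- 0.02
  p_rec <- function(lam, r0) {
    i1m3 <- 2 * lam^2 + lam^(-4) - 3
    dU <- 0
    for (i in seq_along(cb)) dU <- dU + i * cb[i] * i1m3^(i - 1)
    Pb <- 2 * (lam - lam^(-5)) * dU
    (2 * mu / (a * lam^3)) * (lam^a - lam^(-3 * a * beta)) +
      af * 2 * C10 * (lam - lam^(-2)) +
      2 * t0 * Pb / (r0 * lam^2)
  }
  V0 <- rep(geom$V_lobes_mL / n_patches, each = n_patches)
  r0 <- (3 * V0 * 1000 / (4 * pi))^(1 / 3)
  vapply(pressures, function(p) {
    if (p <= 0) return(0)
    sum(vapply(seq_along(V0), function(j) {
      f <- function(l) p_rec(l, r0[j]) - p
      hi <- 1.01
      while (f(hi) < 0) hi <- hi * 1.25
      lam <- stats::uniroot(f, c(1 - 1e-9, hi), tol = 1e-12)$root
      V0[j] * (lam^3 - 1)
    }, numeric(1)))
  }, numeric(1))
}

# Central-difference derivative helper for stress/energy oracles.
central_diff <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)

random_admissible_state <- function() {
  list(p = hyperfoam_params(mu = runif(1, 0.5, 10),
                            alpha = runif(1, 0.5, 8),
                            nu = runif(1, 0, 0.45)),
       stretches = exp(runif(3, log(0.7), log(1.6))))
}
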