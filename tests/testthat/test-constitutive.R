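# Constitutive laws: energies, stresses, conversions, biaxial fitting,
# convexity.

test_that("Poisson ratio to beta conversion matches nu/(1-2nu) and rejects
          the incompressible limit", {
  expect_identical(poisson_ratio_to_beta(0), 0)
  expect_equal(poisson_ratio_to_beta(0.25), 0.5)
  expect_equal(poisson_ratio_to_beta(0.4), 2.0)
  expect_error(poisson_ratio_to_beta(0.5), "0.5")
  expect_error(poisson_ratio_to_beta(-0.01))
  expect_error(poisson_ratio_to_beta(NaN))
})

test_that("hyperfoam energy is zero at the reference state and linear in mu", {
  set.seed(42)
  for (i in 1:20) {
    st <- random_admissible_state()
    expect_identical(hyperfoam_energy(st$p, c(1, 1, 1)), 0)
    U1 <- hyperfoam_energy(st$p, st$stretches)
    p2 <- hyperfoam_params(2 * st$p$mu, st$p$alpha, st$p$nu)
    expect_equal(hyperfoam_energy(p2, st$stretches), 2 * U1)
  }
})

test_that("hyperfoam energy reproduces a high-precision direct evaluation", {
  # (2*1/2^2) * (1.2^2 + 1 + 1 - 3 + (1/0.75)*(1.2^(-2*0.75) - 1)),
  # frozen from an independent direct evaluation
  p <- hyperfoam_params(mu = 1, alpha = 2, nu = 0.3)
  expect_equal(hyperfoam_energy(p, c(1.2, 1, 1)), 0.06048384954182054,
               tolerance = 1e-12)
})

test_that("the volumetric term is continuous across the beta -> 0 branch
          switch", {
  set.seed(7)
  for (i in 1:25) {
    l <- exp(runif(3, log(0.7), log(1.6)))
    mu <- runif(1, 0.5, 5)
    a <- runif(1, 0.5, 8)
    U0 <- hyperfoam_energy(hyperfoam_params(mu, a, 0), l)
    Ue <- hyperfoam_energy(hyperfoam_params(mu, a, 1e-8), l)
    expect_lt(abs(Ue - U0), 1e-6 * (1 + abs(U0)))
  }
})

test_that("principal Cauchy stresses vanish at identity and match central
          finite differences of the energy", {
  p0 <- hyperfoam_params(2.8, 3e-3, 0)
  expect_equal(hyperfoam_principal_stress(p0, c(1, 1, 1)), rep(0, 3))
  fd_stress <- function(p, l, h_rel = 1e-5) {
    J <- prod(l)
    vapply(1:3, function(i) {
      f <- function(x) {
        ll <- l
        ll[i] <- x
        hyperfoam_energy(p, ll)
      }
      (l[i] / J) * central_diff(f, l[i], h_rel * l[i])
    }, numeric(1))
  }
  # tiny alpha: the 2*mu/alpha^2 prefactor amplifies roundoff in the
  # differenced energy, so the oracle uses a larger step there
  sig <- hyperfoam_principal_stress(p0, c(1.3, 1.3, 1.3))
  expect_equal(sig, fd_stress(p0, c(1.3, 1.3, 1.3), h_rel = 2e-4),
               tolerance = 1e-6)
  set.seed(123)
  worst <- 0
  for (i in 1:100) {
    st <- random_admissible_state()
    sig <- hyperfoam_principal_stress(st$p, st$stretches)
    ref <- fd_stress(st$p, st$stretches)
    worst <- max(worst, max(abs(sig - ref)) / max(abs(ref), 1e-8))
  }
  expect_lt(worst, 1e-6)
})

test_that("the small-strain response recovers the initial shear modulus", {
  # isochoric pure shear: stretches (1+e, 1/(1+e), 1);
  # (sigma1 - sigma3) / (2 (eps1 - eps3)) -> mu as e -> 0
  for (nu in c(0, 0.2, 0.4)) {
    p <- hyperfoam_params(mu = 2.8, alpha = 1.7, nu = nu)
    e <- 1e-4
    l <- c(1 + e, 1 / (1 + e), 1)
    sig <- hyperfoam_principal_stress(p, l)
    eps <- l - 1
    mu_app <- (sig[1] - sig[2]) / (2 * (eps[1] - eps[2]))
    expect_equal(mu_app, p$mu, tolerance = 0.01)
  }
})

test_that("the energy Hessian at identity is positive definite on the
          admissible parameter domain", {
  set.seed(99)
  h <- 1e-4
  for (i in 1:10) {
    p <- hyperfoam_params(runif(1, 0.2, 20), runif(1, 0.3, 9),
                          runif(1, 0, 0.49))
    H <- matrix(0, 3, 3)
    f <- function(l) hyperfoam_energy(p, l)
    for (a in 1:3) {
      for (b in 1:3) {
        ea <- eb <- rep(0, 3)
        ea[a] <- h
        eb[b] <- h
        H[a, b] <- (f(c(1, 1, 1) + ea + eb) - f(c(1, 1, 1) + ea - eb) -
                      f(c(1, 1, 1) - ea + eb) + f(c(1, 1, 1) - ea - eb)) /
          (4 * h^2)
      }
    }
    expect_gt(min(eigen(H, symmetric = TRUE)$values), 0)
  }
})

test_that("pleura coefficient scaling reproduces the reported shear moduli", {
  base <- pleura_baseline_default()  # 2*C10 = 2.4 kPa
  expect_equal(initial_shear_modulus(base), 2.4)
  unscaled <- pleura_material(base, scale_lambda = 1)
  expect_identical(scale_reduced_polynomial(unscaled)$coefficients,
                   base$coefficients)
  # lambda = 0.7e-3: 2*lambda*C10 = 1.68 Pa -> 1.7 Pa at two significant
  # figures; lambda = 1.3e-2: 31.2 Pa -> 31 Pa
  m1 <- scale_reduced_polynomial(pleura_material(base, 0.7e-3))
  expect_equal(signif(1000 * initial_shear_modulus(m1), 2), 1.7)
  m2 <- scale_reduced_polynomial(pleura_material(base, 1.3e-2))
  expect_equal(1000 * initial_shear_modulus(m2), 31.2, tolerance = 1e-12)
  expect_equal(round(1000 * initial_shear_modulus(m2)), 31)
})

test_that("initial shear modulus conversions are 2*C10 for C10-based laws
          and mu for the foam", {
  expect_equal(initial_shear_modulus(neo_hookean_params(0.1)), 0.2)
  expect_equal(initial_shear_modulus(neo_hookean_params(0.4)), 0.8)
  expect_equal(initial_shear_modulus(neo_hookean_params(1.1)), 2.2)
  expect_equal(initial_shear_modulus(hyperfoam_params(2.8, 2, 0.3)), 2.8)
  expect_equal(initial_shear_modulus(reduced_polynomial_params(c(0.3, 5))),
               0.6)
})

test_that("equibiaxial nominal stress matches its closed form, its energy
          derivative, and is linear in the coefficients", {
  rp1 <- reduced_polynomial_params(0.1)
  expect_identical(equibiaxial_nominal_stress(rp1, 1), 0)
  expect_equal(equibiaxial_nominal_stress(rp1, 1.2),
               0.2 * (1.2 - 1.2^(-5)), tolerance = 1e-14)
  expect_error(equibiaxial_nominal_stress(rp1, -1), "> 0")

  # P(lam) = (1/2) d/dlam U(I1(lam)) along the incompressible equibiaxial
  # path (two loading directions share the work)
  U_path <- function(rp, lam) {
    i1m3 <- 2 * lam^2 + lam^(-4) - 3
    sum(rp$coefficients * i1m3^seq_along(rp$coefficients))
  }
  set.seed(21)
  worst <- 0
  for (i in 1:30) {
    rp <- reduced_polynomial_params(runif(3, 0.05, 5))
    lam <- runif(1, 1.05, 1.8)
    P <- equibiaxial_nominal_stress(rp, lam)
    P_fd <- 0.5 * central_diff(function(x) U_path(rp, x), lam, 1e-6)
    worst <- max(worst, abs(P - P_fd) / max(abs(P_fd), 1e-10))
    rp2 <- reduced_polynomial_params(2 * rp$coefficients)
    expect_equal(equibiaxial_nominal_stress(rp2, lam), 2 * P)
  }
  expect_lt(worst, 1e-6)
})

test_that("reduced-polynomial fitting is an exact round trip on noiseless
          data and a projection", {
  truth <- reduced_polynomial_params(c(1.2, 6.0))
  strain <- seq(0, 0.6, length.out = 30)
  curve <- data.frame(nominal_strain = strain,
                      nominal_stress_kPa =
                        equibiaxial_nominal_stress(truth, 1 + strain))
  fit <- fit_reduced_polynomial(curve, order = 2)
  expect_equal(fit$coefficients, truth$coefficients, tolerance = 1e-10)

  # order-1 (Neo-Hookean) recovery to linear least-squares accuracy
  nh <- reduced_polynomial_params(0.1)
  c1 <- data.frame(nominal_strain = strain,
                   nominal_stress_kPa =
                     equibiaxial_nominal_stress(nh, 1 + strain))
  f1 <- fit_reduced_polynomial(c1, order = 1)
  expect_equal(f1$coefficients, 0.1, tolerance = 1e-8)

  # projection: refitting the fit's own predictions returns the same
  # coefficients
  noisy <- curve
  set.seed(3)
  noisy$nominal_stress_kPa <- noisy$nominal_stress_kPa + rnorm(30, sd = 2)
  f2 <- fit_reduced_polynomial(noisy, order = 2)
  pred <- data.frame(nominal_strain = strain,
                     nominal_stress_kPa =
                       equibiaxial_nominal_stress(f2, 1 + strain))
  f3 <- fit_reduced_polynomial(pred, order = 2)
  expect_equal(f3$coefficients, f2$coefficients, tolerance = 1e-9)

  expect_error(fit_reduced_polynomial(curve[1, ], order = 2), "ill-posed")
  expect_error(fit_reduced_polynomial(
    data.frame(nominal_strain = c(-0.1, 0.2),
               nominal_stress_kPa = c(0, 1)), order = 1))
})

test_that("fitting a multi-donor synthetic spread lands inside the
          generator's stiffness bounds", {
  ds <- make_biaxial(biaxial_spec(noise_sd_kPa = 0, seed = 11))
  fit <- fit_reduced_polynomial(ds$data, order = 2)
  mods <- 2.4 * ds$truth$donor_multipliers  # per-donor initial shear moduli
  fitted_mod <- initial_shear_modulus(fit)
  expect_gt(fitted_mod, min(mods))
  expect_lt(fitted_mod, max(mods))
})

test_that("convexity verdicts: positive Neo-Hookean convex, strongly
          negative quadratic term flagged, verdict scale-invariant", {
  conv <- check_convexity(reduced_polynomial_params(0.5))
  expect_true(conv$convex)
  bad <- check_convexity(reduced_polynomial_params(c(0.01, -10)))
  expect_false(bad$convex)
  expect_lt(bad$min_eigenvalue, 0)
  # positive scaling leaves the verdict unchanged
  scaled_good <- check_convexity(reduced_polynomial_params(0.5 * 37))
  expect_true(scaled_good$convex)
  scaled_bad <- check_convexity(reduced_polynomial_params(c(0.01, -10) * 37))
  expect_false(scaled_bad$convex)
  expect_error(check_convexity(reduced_polynomial_params(0.5), n_grid = 1),
               "degenerate")
  expect_error(check_convexity(reduced_polynomial_params(0.5),
                               lam_range = c(0.4, 2)))
})

test_that("material constructors enforce their invariants", {
  expect_error(hyperfoam_params(-1, 2, 0.3), "mu")
  expect_error(hyperfoam_params(1, 0, 0.3), "alpha")
  expect_error(hyperfoam_params(1, 2, 0.5))
  expect_error(neo_hookean_params(0), "C10")
  expect_error(reduced_polynomial_params(numeric(0)))
  expect_error(reduced_polynomial_params(c(-1, 2)), "C10")
  expect_error(pleura_material(pleura_baseline_default(), 4), "scale_lambda")
})
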