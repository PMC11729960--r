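# The bounded least-squares loop and its five-criterion termination
# protocol, exercised on constructed toy problems, plus the calibration
# objective's structure.

toy_criteria <- function(...) {
  termination_criteria(n_params = 2, max_fevals = 1e6, ...)
}

test_that("a convex quadratic toy converges to its interior minimiser", {
  cc <- c(2, -1)
  fit <- ls_minimize(function(x) x - cc, c(5, 5), lower = c(-10, -10),
                     upper = c(10, 10), criteria = toy_criteria())
  expect_equal(fit$par, cc, tolerance = 1e-6)
  expect_true(fit$reason %in% c("optimality_tolerance", "step_tolerance",
                                "function_tolerance"))
})

test_that("an exterior minimiser is clipped to the bound and satisfies the
          bound-scaled optimality condition", {
  cc <- c(15, 0)  # outside the box
  fit <- ls_minimize(function(x) x - cc, c(0, 0), lower = c(-10, -10),
                     upper = c(10, 10), criteria = toy_criteria())
  expect_equal(fit$par[1], 10, tolerance = 1e-9)
  expect_equal(fit$par[2], 0, tolerance = 1e-6)
  # KKT at the active bound: gradient pushes outward, v_i = x_i - b_i = 0
  g <- 2 * (fit$par - cc)
  v <- ifelse(g > 0, fit$par - c(-10, -10), ifelse(g < 0, fit$par - 10, 1))
  expect_lt(max(abs(v * g)), 1e-5)
})

test_that("each termination criterion triggers on its constructed toy at
          the printed threshold", {
  # 1. function tolerance: a residual so shallow every objective change is
  #    below 1e-6 * (1 + phi)
  f1 <- ls_minimize(function(x) 1e-9 * x, 5, lower = -10, upper = 10,
                    criteria = termination_criteria(n_params = 1,
                                                    max_fevals = 1e6))
  expect_identical(f1$reason, "function_tolerance")

  # 2. evaluation cap: a cap of 3 is exhausted while assembling the first
  #    Jacobian and trial step
  f2 <- ls_minimize(function(x) x - c(4, 4), c(0, 0), lower = c(-9, -9),
                    upper = c(9, 9),
                    criteria = termination_criteria(n_params = 2,
                                                    max_fevals = 3))
  expect_identical(f2$reason, "max_function_evals")
  expect_lte(f2$fevals, 3 + 1)

  # 3. iteration cap on a slow nonlinear valley (Rosenbrock residuals)
  f3 <- ls_minimize(function(x) c(10 * (x[2] - x[1]^2), 1 - x[1]),
                    c(-1.2, 1), lower = c(-5, -5), upper = c(5, 5),
                    criteria = termination_criteria(
                      n_params = 2, max_fevals = 1e6, max_iterations = 2,
                      function_tol = 1e-16, optimality_tol = 1e-16,
                      step_tol = 1e-16))
  expect_identical(f3$reason, "max_iterations")
  expect_equal(f3$iterations, 3)  # stops once the count exceeds the cap

  # 4. optimality: a nearly flat residual whose gradient magnitude is below
  #    1e-6 after one long step, with bounds close enough that the v_i
  #    scaling stays small
  f4 <- ls_minimize(function(x) 1e-5 * x + 0.03, 0, lower = -4000,
                    upper = 4000,
                    criteria = termination_criteria(n_params = 1,
                                                    max_fevals = 1e6))
  expect_identical(f4$reason, "optimality_tolerance")

  # 5. step tolerance: a steep residual started 3e-4 from its minimum
  #    moves less than 5e-4 while the objective change stays large
  f5 <- ls_minimize(function(x) 1e4 * (x - 3), 3 + 3e-4, lower = 0,
                    upper = 10,
                    criteria = termination_criteria(n_params = 1,
                                                    max_fevals = 1e6))
  expect_identical(f5$reason, "step_tolerance")
})

test_that("termination decisions and traces are exactly reproducible", {
  run <- function() {
    ls_minimize(function(x) c(10 * (x[2] - x[1]^2), 1 - x[1]),
                c(-1.2, 1), lower = c(-5, -5), upper = c(5, 5),
                criteria = toy_criteria())
  }
  a <- run()
  b <- run()
  expect_identical(a$trace, b$trace)
  expect_identical(a$reason, b$reason)
})

test_that("a two-basin toy resolves to the deeper basin under multistart", {
  # residuals (x^2 - 1, 0.1 (x - 1)): local minima near -1 and +1, the +1
  # basin strictly deeper; brute-force grid is the oracle
  resid <- function(x) c(x^2 - 1, 0.1 * (x - 1))
  grid <- seq(-2, 2, by = 1e-3)
  phi_grid <- vapply(grid, function(x) sum(resid(x)^2), numeric(1))
  x_star <- grid[which.min(phi_grid)]
  starts <- c(-0.9, 0.9)
  fits <- lapply(starts, function(s) {
    ls_minimize(resid, s, lower = -2, upper = 2,
                criteria = termination_criteria(n_params = 1,
                                                max_fevals = 1e6))
  })
  phis <- vapply(fits, function(f) f$phi, numeric(1))
  best <- fits[[which.min(phis)]]
  expect_equal(best$par, x_star, tolerance = 1e-2)
  expect_lt(best$phi, 1e-8)
  # the shallower basin really is a distinct local minimum
  expect_gt(max(phis), 0.01)
})

test_that("the default calibration protocol has three starts and the
          printed evaluation cap", {
  expect_length(default_starting_points(), 3)
  expect_identical(termination_criteria()$max_fevals, 900L)
  b <- default_parameter_bounds()
  expect_equal(unname(b$lower[c("mu", "alpha", "nu", "k_UL", "C10",
                                "lambda")]),
               c(0.1, 1e-6, 0, 0.1, 0.1, 1e-6))
  expect_equal(unname(b$upper[c("mu", "alpha", "nu", "k_UL", "C10",
                                "lambda")]),
               c(100, 10, 0.5, 100, 100, 3))
  for (s in default_starting_points()) {
    expect_true(all(s >= b$lower & s <= b$upper))
  }
})

test_that("the calibration objective is deterministic and structurally
          sparse in the permeabilities", {
  th <- test_theta()
  rec <- make_experiment(theta_true = th, geom = small_geometry(),
                         noise = noise_spec(0, 0), n_patches = 2,
                         lobes_seed = 9, n_steps = 60)
  cfg <- forward_config(n_patches = 2, lobes_seed = 9, n_steps = 60)
  o1 <- calibration_objective(th, rec, cfg)
  o2 <- calibration_objective(th, rec, cfg)
  expect_identical(o1$phi, o2$phi)
  expect_equal(o1$phi, 0)

  # perturbing the middle-right permeability touches the shared volume
  # block and only MR's strain components
  th2 <- th
  th2["k_MR"] <- th[["k_MR"]] * 1.3
  r <- calibration_objective(th2, rec, cfg)$residuals
  mr_rows <- which(rep(c("UL", "LL", "UR", "MR", "LR"), each = 3) == "MR")
  strain_idx <- c(20 + mr_rows, 35 + mr_rows)
  other_strain <- setdiff(21:50, strain_idx)
  # other lobes change only through the shared adaptive step sequence of
  # the integrator (O(rtol)); MR changes by orders of magnitude more
  expect_gt(max(abs(r[strain_idx])), 1e-3)
  expect_lt(max(abs(r[other_strain])), 1e-6)

  # an invalid parameter vector is reported as a failed evaluation
  bad <- th
  bad["nu"] <- 0.5
  expect_true(calibration_objective(bad, rec, cfg)$failed)
})

test_that("failed evaluations are absorbed as penalties instead of
          aborting the search", {
  calls <- 0
  resid <- function(x) {
    calls <<- calls + 1
    if (x[1] > 2) return(NULL)  # simulate a forward-model failure region
    x - 1.5
  }
  fit <- ls_minimize(resid, 0.2, lower = 0, upper = 5,
                     criteria = termination_criteria(n_params = 1,
                                                     max_fevals = 200))
  expect_equal(fit$par, 1.5, tolerance = 1e-4)
})

test_that("ranking local minima orders by the mean error triplet and is
          input-order invariant", {
  mk <- function(phi, v, m, s, reason = "step_tolerance") {
    structure(list(phi = phi, reason = reason,
                   breakdown = structure(list(volume_pct = v,
                                              mean_strain_pct = m,
                                              std_strain_pct = s),
                                         class = "error_breakdown")),
              class = "ls_fit")
  }
  perfect <- mk(0, 0, 0, 0)
  mid <- mk(2, 10, 12, 8)
  worse <- mk(1, 30, 40, 20)
  t1 <- rank_minima(list(perfect, mid, worse))
  expect_equal(t1$start[t1$rank == 1], 1)
  expect_equal(t1$mean_error_pct[t1$rank == 1], 0)
  t2 <- rank_minima(list(worse, mid, perfect))
  expect_equal(t2$start[t2$rank == 1], 3)
  expect_equal(t1$mean_error_pct[order(t1$rank)],
               t2$mean_error_pct[order(t2$rank)])
  single <- rank_minima(list(mid))
  expect_equal(single$rank, 1)
})

test_that("sensitivity sweep: zero step means zero effect, out-of-bound
          perturbations are flagged, effects are reproducible", {
  th <- test_theta()
  rec <- make_experiment(theta_true = th, geom = small_geometry(),
                         noise = noise_spec(0, 0), n_patches = 2,
                         lobes_seed = 9, n_steps = 60)
  cfg <- forward_config(n_patches = 2, lobes_seed = 9, n_steps = 60)
  z <- sensitivity_sweep(th, rec, rel_step = 0, config = cfg)
  expect_true(all(z$delta_phi[!z$skipped] == 0))

  th_edge <- th
  th_edge["nu"] <- 0.49
  s <- sensitivity_sweep(th_edge, rec, rel_step = 0.05, config = cfg)
  expect_true(s$skipped[s$parameter == "nu" & s$direction == 1])
  expect_false(s$skipped[s$parameter == "nu" & s$direction == -1])

  s1 <- sensitivity_sweep(th, rec, rel_step = 0.1, config = cfg)
  s2 <- sensitivity_sweep(th, rec, rel_step = 0.1, config = cfg)
  expect_identical(s1, s2)
  # perturbing away from a perfect fit always worsens the objective
  expect_true(all(s1$delta_phi[!s1$skipped] >= 0))
})
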