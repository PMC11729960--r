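# The inverse-calibration loop: bounded nonlinear least squares on the
# material parameter vector, with forward-difference Jacobians, multistart,
# and the five-criterion termination protocol (function tolerance, a
# function-evaluation cap, an iteration cap, a bound-scaled first-order
# optimality measure, and a step tolerance), checked in that order after
# every accepted iteration.

#' Names of the calibrated parameter vector
#'
#' Order: parenchyma `mu` (kPa), `alpha`, `nu`; the five lobe
#' permeabilities `k_UL .. k_LR` (printed 1e-3 mm^2/s scale); airway `C10`
#' (kPa); pleura multiplier `lambda`.
#'
#' @return character(10).
#' @export
parameter_names <- function() {
  c("mu", "alpha", "nu", paste0("k_", LOBE_NAMES), "C10", "lambda")
}

#' Default calibration bounds
#'
#' `mu`, `C10` in \[0.1, 100\] kPa; `alpha` in \[1e-6, 10\]; `nu` in
#' \[0, 0.5\]; each permeability in \[0.1, 100\] (printed scale); `lambda`
#' in \[1e-6, 3\].
#'
#' @return list with named numeric vectors `lower` and `upper`.
#' @export
default_parameter_bounds <- function() {
  lower <- c(mu = 0.1, alpha = 1e-6, nu = 0,
             setNames(rep(0.1, 5), paste0("k_", LOBE_NAMES)),
             C10 = 0.1, lambda = 1e-6)
  upper <- c(mu = 100, alpha = 10, nu = 0.5,
             setNames(rep(100, 5), paste0("k_", LOBE_NAMES)),
             C10 = 100, lambda = 3)
  list(lower = lower, upper = upper)
}

#' Default multistart starting points
#'
#' The three standard starting points of the calibration protocol.
#'
#' @return list of three named parameter vectors.
#' @export
default_starting_points <- function() {
  nm <- parameter_names()
  list(
    setNames(c(5.0, 1.0, 0.0, 10, 10, 10, 10, 10, 1.0, 1.0e-2), nm),
    setNames(c(40, 9.6, 0.4, 79, 39, 69, 49, 12, 7.0, 0.8), nm),
    setNames(c(8.0, 9.7, 0.3, 65, 17, 95, 64, 95, 10, 0.9), nm)
  )
}

#' Termination criteria of the calibration loop
#'
#' The five stopping rules, evaluated in this order after every accepted
#' iteration; the first satisfied rule terminates:
#' 1. function tolerance: `|phi_i - phi_(i+1)| < ftol * (1 + |phi_i|)`;
#' 2. function-evaluation cap (default the protocol's 100 x 9 = 900);
#' 3. iteration cap (default 400);
#' 4. first-order optimality `max_i |v_i g_i| < otol`, where `v_i` is the
#'    distance to the bound the negative gradient points toward (1 if it
#'    points inward) — the bound-scaled measure of reflective trust-region
#'    solvers;
#' 5. step tolerance `max_i |x_i - x_(i+1)| < stol`.
#'
#' @param n_params nominal parameter count for the evaluation cap
#'   (default 9, giving the protocol cap of 900).
#' @param function_tol,optimality_tol relative function and optimality
#'   tolerances (default 1e-6).
#' @param max_fevals evaluation cap (default `100 * n_params`).
#' @param max_iterations iteration cap (default 400).
#' @param step_tol step tolerance (default 5e-4, infinity norm).
#' @return a list of class `termination_criteria`.
#' @export
termination_criteria <- function(n_params = 9L, function_tol = 1e-6,
                                 max_fevals = 100L * n_params,
                                 max_iterations = 400L,
                                 optimality_tol = 1e-6, step_tol = 5e-4) {
  stopifnot(function_tol > 0, max_fevals > 0, max_iterations > 0,
            optimality_tol > 0, step_tol > 0)
  structure(list(function_tol = function_tol,
                 max_fevals = as.integer(max_fevals),
                 max_iterations = as.integer(max_iterations),
                 optimality_tol = optimality_tol, step_tol = step_tol),
            class = "termination_criteria")
}

#' Map a parameter vector to a material set
#'
#' @param theta named numeric(10) in the [parameter_names()] order.
#' @param pleura_baseline baseline pleura coefficients
#'   (default [pleura_baseline_default()]).
#' @param thickness0 pleura reference thickness (mm).
#' @param airway_fraction,heterogeneity_sigma fixed model constants.
#' @return a [material_set()] object.
#' @export
theta_to_materials <- function(theta,
                               pleura_baseline = pleura_baseline_default(),
                               thickness0 = 0.06, airway_fraction = 0.02,
                               heterogeneity_sigma = 0.3) {
  theta <- .check_theta(theta)
  material_set(
    parenchyma = hyperfoam_params(theta[["mu"]], theta[["alpha"]],
                                  theta[["nu"]]),
    permeabilities = theta[paste0("k_", LOBE_NAMES)],
    airways = neo_hookean_params(theta[["C10"]]),
    pleura = pleura_material(pleura_baseline, theta[["lambda"]], thickness0),
    airway_fraction = airway_fraction,
    heterogeneity_sigma = heterogeneity_sigma
  )
}

#' Extract the parameter vector from a material set
#'
#' @param mats a [material_set()] object.
#' @return named numeric(10).
#' @export
materials_to_theta <- function(mats) {
  stopifnot(inherits(mats, "material_set"))
  setNames(c(mats$parenchyma$mu, mats$parenchyma$alpha, mats$parenchyma$nu,
             unname(mats$permeabilities), mats$airways$C10,
             mats$pleura$scale_lambda),
           parameter_names())
}

.check_theta <- function(theta) {
  nm <- parameter_names()
  if (is.null(names(theta))) {
    if (length(theta) != 10) stop("theta must have 10 components",
                                  call. = FALSE)
    names(theta) <- nm
  }
  if (!all(nm %in% names(theta))) {
    stop("theta must carry the names ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  theta[nm]
}

#' Forward-model configuration used inside the calibration
#'
#' @param n_patches patches per lobe (default 20).
#' @param lobes_seed seed for the patch permeability multipliers; `NULL`
#'   means take it from the experiment's provenance (synthetic records).
#' @param n_steps output intervals of the forward integration (default 100).
#' @param rtol,atol integrator tolerances. Tighter than the simulation
#'   defaults so forward-difference Jacobian columns are not drowned in
#'   integration noise.
#' @param pleura_baseline,thickness0,airway_fraction,heterogeneity_sigma
#'   fixed constants passed to [theta_to_materials()].
#' @return a list of class `forward_config`.
#' @export
forward_config <- function(n_patches = 20L, lobes_seed = NULL,
                           n_steps = 100L, rtol = 1e-8, atol = 1e-10,
                           pleura_baseline = pleura_baseline_default(),
                           thickness0 = 0.06, airway_fraction = 0.02,
                           heterogeneity_sigma = 0.3) {
  structure(list(n_patches = as.integer(n_patches), lobes_seed = lobes_seed,
                 n_steps = as.integer(n_steps), rtol = rtol, atol = atol,
                 pleura_baseline = pleura_baseline, thickness0 = thickness0,
                 airway_fraction = airway_fraction,
                 heterogeneity_sigma = heterogeneity_sigma),
            class = "forward_config")
}

.config_seed <- function(exp, config) {
  if (!is.null(config$lobes_seed)) return(as.integer(config$lobes_seed))
  s <- exp$provenance$lobes_seed
  if (is.null(s)) 1L else as.integer(s)
}

#' Run the forward model for a parameter vector against an experiment
#'
#' Deterministic given `(theta, exp, config)`: the patch multipliers are
#' regenerated from the experiment's recorded seed, the simulation runs on
#' the experiment's ramp and geometry, and the normalised residual vector
#' is assembled.
#'
#' @param theta named numeric(10) parameter vector.
#' @param exp an [experiment_record()].
#' @param config a [forward_config()].
#' @return list with `phi`, `residuals`, `breakdown`, `failed` (logical;
#'   a failed forward evaluation returns `residuals = NULL` and
#'   `phi = NA` — the optimizer substitutes its penalty).
#' @export
calibration_objective <- function(theta, exp, config = forward_config()) {
  stopifnot(inherits(exp, "experiment_record"))
  out <- tryCatch({
    mats <- theta_to_materials(theta, config$pleura_baseline,
                               config$thickness0, config$airway_fraction,
                               config$heterogeneity_sigma)
    lobes <- build_lobes(exp$geometry, mats, config$n_patches,
                         .config_seed(exp, config))
    sim <- simulate_inflation(lobes, mats, exp$ramp, config$n_steps,
                              config$rtol, config$atol)
    r <- residual_vector(exp, sim)
    list(phi = attr(r, "phi"), residuals = r,
         breakdown = error_breakdown(exp, sim), failed = FALSE)
  }, error = function(e) {
    list(phi = NA_real_, residuals = NULL, breakdown = NULL, failed = TRUE,
         message = conditionMessage(e))
  })
  out
}

#' Bounded least squares with the five-criterion termination protocol
#'
#' A damped Gauss-Newton (Levenberg-Marquardt) iteration on a residual
#' function, with box bounds enforced by projection, forward-difference
#' Jacobians with per-parameter steps of `fd_rel x (bound width)`, and the
#' termination rules of [termination_criteria()] checked in their printed
#' order after every accepted step. Failed residual evaluations (the
#' function returns `NULL`) are assigned the penalty
#' `1e6 * (1 + best phi so far)` so the search continues.
#'
#' @param resid_fn function mapping a parameter vector to a numeric
#'   residual vector (or `NULL` on failure).
#' @param x0 start, within bounds.
#' @param lower,upper bounds (finite, `lower < upper`).
#' @param criteria a [termination_criteria()] object.
#' @param control list: `lambda0` initial damping (1e-3), `lambda_up` (4),
#'   `lambda_down` (3), `fd_rel` forward-difference step fraction (1e-6),
#'   `max_reject` trial steps per iteration (25).
#' @return list of class `ls_fit`: `par`, `phi`, `residuals`, `iterations`,
#'   `fevals`, `reason`, `trace` (one row per accepted iteration).
#' @export
ls_minimize <- function(resid_fn, x0, lower, upper,
                        criteria = termination_criteria(length(x0)),
                        control = list()) {
  ctl <- modifyList(list(lambda0 = 1e-3, lambda_up = 4, lambda_down = 3,
                         fd_rel = 1e-6, max_reject = 25L), control)
  n <- length(x0)
  stopifnot(length(lower) == n, length(upper) == n, all(lower < upper),
            all(is.finite(lower)), all(is.finite(upper)))
  if (any(x0 < lower - 1e-12) || any(x0 > upper + 1e-12)) {
    stop("start is outside the bounds", call. = FALSE)
  }
  x <- pmin(pmax(x0, lower), upper)
  nfev <- 0L
  best_phi <- Inf
  evaluate <- function(xx) {
    nfev <<- nfev + 1L
    r <- resid_fn(xx)
    if (is.null(r) || any(!is.finite(r))) {
      return(list(r = NULL, phi = 1e6 * (1 + if (is.finite(best_phi))
        best_phi else 0), failed = TRUE))
    }
    phi <- sum(r^2)
    if (phi < best_phi) best_phi <<- phi
    list(r = r, phi = phi, failed = FALSE)
  }

  cur <- evaluate(x)
  if (cur$failed) stop("residual evaluation failed at the start",
                       call. = FALSE)
  lam_damp <- ctl$lambda0
  h <- ctl$fd_rel * (upper - lower)
  iter <- 0L
  reason <- NULL
  trace <- list()

  while (is.null(reason)) {
    iter <- iter + 1L
    # forward-difference Jacobian (switches to backward at the upper bound)
    J <- matrix(0, nrow = length(cur$r), ncol = n)
    for (j in seq_len(n)) {
      hj <- if (x[j] + h[j] <= upper[j]) h[j] else -h[j]
      xj <- x
      xj[j] <- xj[j] + hj
      ev <- evaluate(xj)
      if (!ev$failed) J[, j] <- (ev$r - cur$r) / hj
      if (nfev > criteria$max_fevals) break
    }
    if (nfev > criteria$max_fevals) { reason <- "max_function_evals"; break }

    g <- 2 * drop(crossprod(J, cur$r))
    A <- crossprod(J)
    dA <- diag(A)
    dA[dA == 0] <- 1e-12

    accepted <- FALSE
    rejects <- 0L
    while (!accepted && rejects <= ctl$max_reject) {
      step <- tryCatch(
        solve(A + lam_damp * diag(dA, n), -drop(crossprod(J, cur$r))),
        error = function(e) NULL)
      if (is.null(step)) {
        lam_damp <- lam_damp * ctl$lambda_up
        rejects <- rejects + 1L
        next
      }
      x_new <- pmin(pmax(x + step, lower), upper)
      ev <- evaluate(x_new)
      if (nfev > criteria$max_fevals) { reason <- "max_function_evals"; break }
      if (!ev$failed && ev$phi < cur$phi) {
        accepted <- TRUE
        lam_damp <- max(lam_damp / ctl$lambda_down, 1e-12)
      } else {
        lam_damp <- lam_damp * ctl$lambda_up
        rejects <- rejects + 1L
      }
    }
    if (!is.null(reason)) break
    if (!accepted) {
      # no admissible descent step: treat as converged in step
      reason <- "step_tolerance"
      break
    }

    phi_old <- cur$phi
    x_old <- x
    x <- x_new
    cur <- ev
    trace[[iter]] <- c(iter = iter, phi = cur$phi, fevals = nfev, x)

    # the five termination rules, in printed order
    if (abs(phi_old - cur$phi) <
        criteria$function_tol * (1 + abs(phi_old))) {
      reason <- "function_tolerance"
    } else if (nfev > criteria$max_fevals) {
      reason <- "max_function_evals"
    } else if (iter > criteria$max_iterations) {
      reason <- "max_iterations"
    } else {
      g_new <- 2 * drop(crossprod(J, cur$r))
      v <- ifelse(g_new > 0, x - lower, ifelse(g_new < 0, x - upper, 1))
      if (max(abs(v * g_new)) < criteria$optimality_tol) {
        reason <- "optimality_tolerance"
      } else if (max(abs(x - x_old)) < criteria$step_tol) {
        reason <- "step_tolerance"
      }
    }
  }

  trace_df <- if (length(trace)) {
    as.data.frame(do.call(rbind, trace))
  } else {
    data.frame()
  }
  structure(list(par = x, phi = cur$phi, residuals = cur$r,
                 iterations = iter, fevals = nfev, reason = reason,
                 trace = trace_df),
            class = "ls_fit")
}

#' Single-start calibration of the lung model
#'
#' Runs [ls_minimize()] on [calibration_objective()] residuals from one
#' starting point.
#'
#' @param start named parameter vector within bounds.
#' @param exp an [experiment_record()].
#' @param bounds list with `lower`/`upper` (default
#'   [default_parameter_bounds()]).
#' @param criteria a [termination_criteria()].
#' @param config a [forward_config()].
#' @param control passed to [ls_minimize()].
#' @return an `ls_fit` augmented with `breakdown` (the error triplet at the
#'   solution) and `start`.
#' @export
minimize_single <- function(start, exp,
                            bounds = default_parameter_bounds(),
                            criteria = termination_criteria(),
                            config = forward_config(), control = list()) {
  start <- .check_theta(start)
  resid_fn <- function(theta) {
    names(theta) <- parameter_names()
    calibration_objective(theta, exp, config)$residuals
  }
  fit <- ls_minimize(resid_fn, start, bounds$lower[parameter_names()],
                     bounds$upper[parameter_names()], criteria, control)
  names(fit$par) <- parameter_names()
  sol <- calibration_objective(fit$par, exp, config)
  fit$breakdown <- sol$breakdown
  fit$start <- start
  fit
}

#' Multistart calibration
#'
#' Runs [minimize_single()] independently from each starting point
#' (default: the three standard starts) and selects the lowest-objective
#' local minimum; the error triplet is reported for every start.
#'
#' @inheritParams minimize_single
#' @param starts list of starting vectors (default
#'   [default_starting_points()]).
#' @return an object of class `calibration_outcome`: list with `entries`
#'   (per-start fits), `best_index`, `best` and `total_fevals`.
#' @export
multistart_calibrate <- function(exp, starts = default_starting_points(),
                                 bounds = default_parameter_bounds(),
                                 criteria = termination_criteria(),
                                 config = forward_config(),
                                 control = list()) {
  stopifnot(length(starts) >= 1)
  entries <- lapply(starts, function(s) {
    tryCatch(minimize_single(s, exp, bounds, criteria, config, control),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "ls_fit_failed"))
  })
  ok <- !vapply(entries, inherits, logical(1), "ls_fit_failed")
  if (!any(ok)) {
    stop("all starts failed: ",
         paste(vapply(entries, function(e) e$error, character(1)),
               collapse = " | "), call. = FALSE)
  }
  phis <- vapply(entries, function(e) {
    if (inherits(e, "ls_fit_failed")) Inf else e$phi
  }, numeric(1))
  structure(list(entries = entries, best_index = which.min(phis),
                 best = entries[[which.min(phis)]],
                 total_fevals = sum(vapply(entries, function(e) {
                   if (inherits(e, "ls_fit_failed")) 0L else e$fevals
                 }, integer(1)))),
            class = "calibration_outcome")
}

#' Rank local minima by their mean error triplet
#'
#' Orders calibration solutions by the mean of the three block errors
#' (volume, mean strain, strain std), ties broken by objective value;
#' input order does not affect the ranking.
#'
#' @param outcome a [multistart_calibrate()] result (or a list of
#'   `ls_fit` entries).
#' @return data frame with one row per solution: start index, objective,
#'   the error triplet, the mean error and the rank.
#' @export
rank_minima <- function(outcome) {
  entries <- if (inherits(outcome, "calibration_outcome")) {
    outcome$entries
  } else {
    outcome
  }
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    if (inherits(e, "ls_fit_failed") || is.null(e$breakdown)) {
      data.frame(start = i, phi = NA_real_, volume_pct = NA_real_,
                 mean_strain_pct = NA_real_, std_strain_pct = NA_real_,
                 mean_error_pct = Inf, reason = "failed",
                 stringsAsFactors = FALSE)
    } else {
      b <- e$breakdown
      data.frame(start = i, phi = e$phi, volume_pct = b$volume_pct,
                 mean_strain_pct = b$mean_strain_pct,
                 std_strain_pct = b$std_strain_pct,
                 mean_error_pct = mean(c(b$volume_pct, b$mean_strain_pct,
                                         b$std_strain_pct)),
                 reason = e$reason, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$mean_error_pct, tab$phi)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' One-at-a-time sensitivity sweep around a parameter vector
#'
#' Perturbs each parameter by `+/- rel_step` (relative), re-evaluates the
#' objective, and reports the change in the objective and in each error
#' block. Perturbations that would leave the bounds are skipped and
#' flagged.
#'
#' @param theta named parameter vector (interior point).
#' @param exp an [experiment_record()].
#' @param rel_step relative perturbation (default 0.05).
#' @param config a [forward_config()].
#' @param bounds parameter bounds.
#' @return data frame with one row per parameter and direction:
#'   `parameter`, `direction`, `skipped`, `delta_phi`, `delta_volume_pct`,
#'   `delta_mean_strain_pct`, `delta_std_strain_pct`.
#' @export
sensitivity_sweep <- function(theta, exp, rel_step = 0.05,
                              config = forward_config(),
                              bounds = default_parameter_bounds()) {
  theta <- .check_theta(theta)
  base <- calibration_objective(theta, exp, config)
  if (base$failed) stop("objective failed at the sweep centre", call. = FALSE)
  nm <- parameter_names()
  rows <- list()
  for (j in seq_along(nm)) {
    for (dir in c(-1, 1)) {
      th <- theta
      th[j] <- theta[j] * (1 + dir * rel_step)
      skipped <- th[j] < bounds$lower[nm[j]] || th[j] > bounds$upper[nm[j]]
      if (skipped) {
        d <- rep(NA_real_, 4)
      } else if (rel_step == 0) {
        d <- rep(0, 4)  # unperturbed: effects are identically zero
      } else {
        ev <- calibration_objective(th, exp, config)
        d <- c(ev$phi - base$phi,
               ev$breakdown$volume_pct - base$breakdown$volume_pct,
               ev$breakdown$mean_strain_pct - base$breakdown$mean_strain_pct,
               ev$breakdown$std_strain_pct - base$breakdown$std_strain_pct)
      }
      rows[[length(rows) + 1]] <- data.frame(
        parameter = nm[j], direction = dir, skipped = skipped,
        delta_phi = d[1], delta_volume_pct = d[2],
        delta_mean_strain_pct = d[3], delta_std_strain_pct = d[4],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.ls_fit <- function(x, ...) {
  cat(sprintf("Least-squares fit: phi = %.6g after %d iterations, %d evals (%s)\n",
              x$phi, x$iterations, x$fevals, x$reason))
  invisible(x)
}

#' @export
print.calibration_outcome <- function(x, ...) {
  cat(sprintf("Multistart calibration: %d starts, best = start %d (phi = %.6g), %d total evals\n",
              length(x$entries), x$best_index, x$best$phi, x$total_fevals))
  invisible(x)
}
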