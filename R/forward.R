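# Reduced-order five-lobe poroelastic inflation. Each lobe is split into
# parallel spherical patch compartments; tracheal pressure drives
# permeability-limited airflow into each patch against the elastic recoil of
# hyperfoam parenchyma, an embedded-airway surrogate and the pleural
# membrane (Laplace law). Outputs: PV history and lobe strain statistics.
#
# Units: pressures kPa, volumes mL, radii mm, times s. The compartment flux
#   dV/dt = 4*pi*r0*lam * k * (p_tr - p_rec) / p_ref        [mL/s]
# keeps the permeabilities k at their printed numeric scale (their tabulated
# unit, 1e-3 mm^2/s, is not dimensionally closed against kPa gradients; the
# p_ref = 1 kPa normalisation and the mL/s reading of the conductance are
# the model's closure — see the methods vignette).

#' Material set for the five-lobe model
#'
#' @param parenchyma a [hyperfoam_params()] object.
#' @param permeabilities five lobe permeabilities in the order UL, LL, UR,
#'   MR, LR, at the printed numeric scale (1e-3 mm^2/s), each within
#'   (0, Inf); calibration additionally restricts them to `[0.1, 100]`.
#' @param airways a [neo_hookean_params()] object.
#' @param pleura a [pleura_material()] object.
#' @param airway_fraction volumetric weight of the uniaxial airway
#'   surrogate; fixed model constant, default 0.02.
#' @param heterogeneity_sigma lognormal sigma of the per-patch permeability
#'   multipliers; fixed model constant, default 0.3 (not calibrated).
#' @return an object of class `material_set`.
#' @export
material_set <- function(parenchyma, permeabilities, airways, pleura,
                         airway_fraction = 0.02, heterogeneity_sigma = 0.3) {
  stopifnot(inherits(parenchyma, "hyperfoam_params"),
            inherits(airways, "neo_hookean_params"),
            inherits(pleura, "pleura_material"))
  permeabilities <- as.numeric(permeabilities)
  if (length(permeabilities) != 5 || any(!is.finite(permeabilities)) ||
      any(permeabilities < 0)) {
    stop("`permeabilities` must be five nonnegative values (UL,LL,UR,MR,LR)",
         call. = FALSE)
  }
  names(permeabilities) <- LOBE_NAMES
  if (airway_fraction < 0) stop("`airway_fraction` must be >= 0",
                                call. = FALSE)
  if (heterogeneity_sigma < 0) stop("`heterogeneity_sigma` must be >= 0",
                                    call. = FALSE)
  structure(list(parenchyma = parenchyma, permeabilities = permeabilities,
                 airways = airways, pleura = pleura,
                 airway_fraction = airway_fraction,
                 heterogeneity_sigma = heterogeneity_sigma),
            class = "material_set")
}

#' Pressure ramp applied at the trachea
#'
#' @param times increasing times (s), starting at 0.
#' @param pressures nondecreasing tracheal pressures (kPa), starting at 0.
#' @param shape optional label ("smoothstep", "linear", "custom").
#' @return an object of class `pressure_ramp` with fields `times`,
#'   `pressures`, `p_max`, `duration`.
#' @seealso [make_ramp()] for the standard parametric ramps.
#' @export
pressure_ramp <- function(times, pressures, shape = "custom") {
  stopifnot(is.numeric(times), is.numeric(pressures),
            length(times) == length(pressures), length(times) >= 2)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must increase from 0", call. = FALSE)
  }
  if (pressures[1] != 0 || any(diff(pressures) < -1e-12)) {
    stop("`pressures` must be nondecreasing from 0", call. = FALSE)
  }
  structure(list(times = times, pressures = pressures,
                 p_max = pressures[length(pressures)],
                 duration = times[length(times)], shape = shape),
            class = "pressure_ramp")
}

#' Split the lobes into spherical patch compartments
#'
#' Each lobe becomes `n_patches` parallel sub-compartments of equal initial
#' volume, each an equivalent sphere of radius `r0 = (3 V0 / 4 pi)^(1/3)`
#' (mm). Patch permeability is the lobe permeability times a lognormal
#' multiplier (median 1, sigma = `heterogeneity_sigma`) drawn once from
#' `seed`, standing in for sub-lobar ventilation heterogeneity.
#'
#' @param geom a [lung_geometry()] object.
#' @param mats a [material_set()] object.
#' @param n_patches patches per lobe, `>= 1` (default 20).
#' @param seed integer seed for the multipliers; the draw is local (the
#'   caller's RNG state is untouched).
#' @return a data frame of class `lobe_patches` with one row per patch:
#'   `patch`, `lobe`, `V0_mL`, `r0_mm`, `k_lobe`, `multiplier`, `k_patch`.
#' @export
build_lobes <- function(geom, mats, n_patches = 20L, seed = 1L) {
  stopifnot(inherits(geom, "lung_geometry"), inherits(mats, "material_set"))
  n_patches <- as.integer(n_patches)
  if (is.na(n_patches) || n_patches < 1) {
    stop("`n_patches` must be >= 1", call. = FALSE)
  }
  lobe <- rep(LOBE_NAMES, each = n_patches)
  V0 <- rep(geom$V_lobes_mL / n_patches, each = n_patches)
  mult <- with_seed(seed, exp(rnorm(length(lobe), mean = 0,
                                    sd = mats$heterogeneity_sigma)))
  k_lobe <- rep(mats$permeabilities, each = n_patches)
  out <- data.frame(
    patch = seq_along(lobe),
    lobe = factor(lobe, levels = LOBE_NAMES),
    V0_mL = V0,
    r0_mm = (3 * V0 * 1000 / (4 * pi))^(1 / 3),
    k_lobe = k_lobe,
    multiplier = mult,
    k_patch = k_lobe * mult,
    stringsAsFactors = FALSE
  )
  attr(out, "n_patches") <- n_patches
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("lobe_patches", "data.frame")
  out
}

#' Elastic recoil pressure of a spherical patch
#'
#' The pressure the compartment skeleton exerts against inflation at
#' isotropic stretch `lam`, composed of three terms:
#' * hyperfoam Cauchy stress
#'   `sigma_foam = (2 mu / (alpha lam^3)) (lam^alpha - lam^(-3 alpha beta))`,
#' * a uniaxial Neo-Hookean airway surrogate
#'   `airway_fraction * 2 C10 (lam - lam^-2)`,
#' * the Laplace membrane term `2 t0 P_b(lam) / (r0 lam^2)` with `P_b` the
#'   scaled-pleura equibiaxial nominal stress.
#'
#' Zero at `lam = 1`; `lam < 1` returns negative recoil.
#'
#' @param mats a [material_set()] object.
#' @param lam isotropic stretch(es), `> 0`. Vectorised.
#' @param r0 reference patch radius (mm); scalar or same length as `lam`.
#' @return recoil pressure (kPa).
#' @export
recoil_pressure <- function(mats, lam, r0) {
  stopifnot(inherits(mats, "material_set"))
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("`lam` must be finite and > 0", call. = FALSE)
  }
  .recoil_pressure(mats$parenchyma, mats$airways,
                   scale_reduced_polynomial(mats$pleura),
                   mats$pleura$thickness0, mats$airway_fraction, lam, r0)
}

# Internal recoil with the scaled pleura precomputed (hot loop of the ODE).
.recoil_pressure <- function(foam, airways, pleura_scaled, t0, airway_fraction,
                             lam, r0) {
  a <- foam$alpha
  sigma_foam <- (2 * foam$mu / (a * lam^3)) *
    (lam^a - lam^(-3 * a * foam$beta))
  p_air <- airway_fraction * 2 * airways$C10 * (lam - lam^(-2))
  Pb <- equibiaxial_nominal_stress(pleura_scaled, lam)
  p_mem <- 2 * t0 * Pb / (r0 * lam^2)
  sigma_foam + p_air + p_mem
}

#' Simulate five-lobe poroelastic inflation
#'
#' Integrates, per patch, the quasi-static filling law
#' `dV/dt = 4 pi r0 lam * k_patch * (p_tr(t) - p_rec(lam)) / p_ref` with
#' `lam = (V/V0)^(1/3)`, using an adaptive stiff-capable integrator
#' (`deSolve::ode`, lsoda). An optional Forchheimer coefficient divides the
#' Darcy flux by `1 + beta_F * |q_darcy|` (velocity-dependent drag); the
#' default 0 is the Darcy limit.
#'
#' @param lobes a [build_lobes()] patch table.
#' @param mats a [material_set()] object.
#' @param ramp a [pressure_ramp()] object.
#' @param n_steps number of output intervals over the ramp (`>= 50`,
#'   default 100).
#' @param rtol,atol integrator tolerances (defaults 1e-6 and 1e-9 mL).
#' @param forchheimer_beta optional Forchheimer drag coefficient (s/mL),
#'   default 0.
#' @return an object of class `forward_result`: `times`, `p_tr`, matrices
#'   `V`, `lam`, `p_pore` (time x patch), aggregate `V_added_mL`, plus the
#'   inputs needed downstream (`lobes`, `ramp`).
#' @export
simulate_inflation <- function(lobes, mats, ramp, n_steps = 100L,
                               rtol = 1e-6, atol = 1e-9,
                               forchheimer_beta = 0) {
  stopifnot(inherits(lobes, "lobe_patches"), inherits(mats, "material_set"),
            inherits(ramp, "pressure_ramp"))
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 50) {
    stop("`n_steps` must be >= 50", call. = FALSE)
  }
  V0 <- lobes$V0_mL
  r0 <- lobes$r0_mm
  k <- lobes$k_patch
  p_fun <- approxfun(ramp$times, ramp$pressures, rule = 2)
  pleura_scaled <- scale_reduced_polynomial(mats$pleura)
  foam <- mats$parenchyma
  airways <- mats$airways
  t0 <- mats$pleura$thickness0
  af <- mats$airway_fraction

  rhs <- function(t, V, parms) {
    lam <- (V / V0)^(1 / 3)
    p_rec <- .recoil_pressure(foam, airways, pleura_scaled, t0, af, lam, r0)
    q <- 4 * pi * r0 * lam * k * (p_fun(t) - p_rec) / P_REF_KPA
    if (forchheimer_beta > 0) q <- q / (1 + forchheimer_beta * abs(q))
    list(q)
  }

  times <- seq(0, ramp$duration, length.out = n_steps + 1)
  sol <- deSolve::ode(y = V0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  V <- unname(sol[, -1, drop = FALSE])
  if (nrow(V) < length(times) || anyNA(V)) {
    bad_row <- if (anyNA(V)) which(apply(V, 1, anyNA))[1] else nrow(V) + 1
    bad_patch <- if (bad_row <= nrow(V)) which(is.na(V[bad_row, ]))[1] else NA
    stop(sprintf(
      "inflation solver failed to converge near t = %.4g s (patch %s, lobe %s)",
      times[min(bad_row, length(times))], bad_patch,
      if (!is.na(bad_patch)) as.character(lobes$lobe[bad_patch]) else "?"),
      call. = FALSE)
  }
  lam <- sweep(V, 2, V0, "/")^(1 / 3)
  p_pore <- t(apply(lam, 1, function(l) {
    .recoil_pressure(foam, airways, pleura_scaled, t0, af, l, r0)
  }))
  structure(list(
    times = times,
    p_tr = p_fun(times),
    V = V,
    lam = lam,
    p_pore = p_pore,
    V_added_mL = rowSums(V) - sum(V0),
    lobes = lobes,
    ramp = ramp,
    rtol = rtol, atol = atol
  ), class = "forward_result")
}

#' Sample a pressure-volume curve from a simulation
#'
#' `n` pressure/volume pairs at times uniform over the ramp duration.
#' Volumes are added volume (the initial volume is zeroed, as in the
#' ventilation experiments), so the first sampled volume is exactly 0.
#'
#' @param result a [simulate_inflation()] result.
#' @param n number of pairs, `>= 2` (default 20).
#' @return data frame with columns `t_s`, `p_kPa`, `V_added_mL`.
#' @export
sample_pv <- function(result, n = 20L) {
  stopifnot(inherits(result, "forward_result"))
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
  t_s <- seq(0, result$ramp$duration, length.out = n)
  V <- approx(result$times, result$V_added_mL, xout = t_s)$y
  V[1] <- 0
  data.frame(
    t_s = t_s,
    p_kPa = approx(result$ramp$times, result$ramp$pressures, xout = t_s,
                   rule = 2)$y,
    V_added_mL = V
  )
}

#' Lobe-wise major-strain statistics at the inflation stages
#'
#' Locates the times at which the tracheal pressure first reaches 30%, 60%
#' and 100% of its peak (linear interpolation of the monotone ramp),
#' interpolates each patch's stretch there, and summarises the major nominal
#' strain `lam - 1` per lobe as mean and population standard deviation over
#' patches: exactly 15 means and 15 standard deviations.
#'
#' @param result a [simulate_inflation()] result.
#' @return a data frame of class `lobe_strain_stats` with 15 rows and
#'   columns `lobe`, `stage_fraction`, `mean_strain`, `std_strain`, ordered
#'   lobe-major (UL, LL, UR, MR, LR), stage-minor (0.3, 0.6, 1.0).
#' @export
extract_strain_stats <- function(result) {
  stopifnot(inherits(result, "forward_result"))
  p_max <- result$ramp$p_max
  if (p_max <= 0) stop("ramp peak pressure must be > 0", call. = FALSE)
  p <- result$p_tr
  times <- result$times
  stage_t <- vapply(STAGE_FRACTIONS, function(f) {
    if (f >= 1) return(times[length(times)])
    target <- f * p_max
    i <- which(p >= target)[1]
    if (i == 1) return(times[1])
    # linear interpolation between the bracketing output times
    times[i - 1] + (times[i] - times[i - 1]) *
      (target - p[i - 1]) / (p[i] - p[i - 1])
  }, numeric(1))
  lam_stage <- apply(result$lam, 2, function(l) {
    approx(times, l, xout = stage_t)$y
  })
  lam_stage <- matrix(lam_stage, nrow = length(stage_t))
  lobe <- result$lobes$lobe
  rows <- lapply(LOBE_NAMES, function(lb) {
    idx <- which(lobe == lb)
    do.call(rbind, lapply(seq_along(STAGE_FRACTIONS), function(si) {
      strains <- lam_stage[si, idx] - 1
      data.frame(lobe = lb, stage_fraction = STAGE_FRACTIONS[si],
                 mean_strain = mean(strains),
                 std_strain = sqrt(mean((strains - mean(strains))^2)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$lobe <- factor(out$lobe, levels = LOBE_NAMES)
  class(out) <- c("lobe_strain_stats", "data.frame")
  out
}

#' @export
print.material_set <- function(x, ...) {
  cat("Material set\n  parenchyma: ")
  print(x$parenchyma)
  cat("  airways:    ")
  print(x$airways)
  cat("  pleura:     ")
  print(x$pleura)
  cat(sprintf("  permeabilities (1e-3 mm^2/s): %s\n",
              paste(sprintf("%s %.3g", LOBE_NAMES, x$permeabilities),
                    collapse = ", ")))
  cat(sprintf("  airway_fraction = %g, heterogeneity_sigma = %g\n",
              x$airway_fraction, x$heterogeneity_sigma))
  invisible(x)
}

#' @export
print.forward_result <- function(x, ...) {
  cat(sprintf(
    "Inflation: %d patches, %.3g s ramp to %.3g kPa, V_added(final) = %.1f mL\n",
    ncol(x$V), x$ramp$duration, x$ramp$p_max,
    x$V_added_mL[length(x$V_added_mL)]))
  invisible(x)
}
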