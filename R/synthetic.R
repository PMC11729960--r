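# Synthetic study generators: pressure ramps, ventilation experiments with
# known ground-truth materials, and pleura equibiaxial datasets. These are
# first-class, tested code — every downstream stage (metrics, calibration)
# is exercised against records whose generating parameters are stored in
# their provenance.

#' Build a standard tracheal pressure ramp
#'
#' Defaults are the study conditions: peak pressure 2.1 kPa reached over a
#' 2 s inflation (15 breaths/min). The default waveform is the smoothstep
#' `p_max * (3 s^2 - 2 s^3)` with `s = t / duration` (zero slope at both
#' ends, like a piston spin-up); a linear ramp is available.
#'
#' @param p_max peak pressure (kPa), `> 0`; default 2.1.
#' @param duration ramp duration (s); default 2.
#' @param shape "smoothstep" (default) or "linear".
#' @param n_steps number of tabulation intervals (default 200).
#' @return a [pressure_ramp()] object.
#' @export
make_ramp <- function(p_max = 2.1, duration = 2,
                      shape = c("smoothstep", "linear"), n_steps = 200L) {
  shape <- match.arg(shape)
  if (p_max <= 0) stop("`p_max` must be > 0", call. = FALSE)
  s <- seq(0, 1, length.out = n_steps + 1)
  p <- switch(shape,
              smoothstep = p_max * (3 * s^2 - 2 * s^3),
              linear = p_max * s)
  pressure_ramp(times = s * duration, pressures = p, shape = shape)
}

#' Measurement-noise specification for synthetic experiments
#'
#' Gaussian and independent per component: volumes get relative noise,
#' strain statistics absolute noise. The experimental noise floors of
#' ventilation rigs and surface-strain imaging are not published; these
#' defaults are order-of-magnitude choices, exposed here for configuration.
#'
#' @param pv_rel_sd relative sd of the volume noise (default 0.02).
#' @param strain_abs_sd absolute sd of the strain-statistic noise
#'   (default 0.005).
#' @param seed integer seed for the noise draws.
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(pv_rel_sd = 0.02, strain_abs_sd = 0.005, seed = 1L) {
  stopifnot(pv_rel_sd >= 0, strain_abs_sd >= 0)
  structure(list(pv_rel_sd = pv_rel_sd, strain_abs_sd = strain_abs_sd,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Default ground-truth parameter vector of the synthetic study
#'
#' The generating materials of the default synthetic donor: parenchyma
#' `mu = 2.8` kPa (the calibrated human parenchymal shear-modulus scale),
#' `alpha = 9`, `nu = 0.3`; lobe permeabilities `(2, 1.5, 1.2, 5, 1.5)`
#' for (UL, LL, UR, MR, LR) — the middle right lobe the most permeable;
#' airway `C10 = 1` kPa; pleura multiplier `lambda = 0.5`. Under the
#' standard 2.1 kPa / 2 s ramp these produce an S-shaped PV curve (~2 L
#' added volume with lower and upper inflection points) and lobe strains
#' of order 0.05-0.25 with nonzero within-lobe spread — a record shaped
#' like a cadaveric-lung ventilation experiment. All values are interior
#' to the calibration bounds. See the methods vignette for how they were
#' chosen.
#'
#' @return named numeric(10).
#' @export
default_true_theta <- function() {
  setNames(c(2.8, 9.0, 0.3, 2.0, 1.5, 1.2, 5.0, 1.5, 1.0, 0.5),
           parameter_names())
}

#' Apply measurement noise to clean PV and strain tables
#'
#' Volumes are multiplied by `1 + N(0, pv_rel_sd)` (the zeroed first point
#' stays 0); strain means and standard deviations receive additive
#' `N(0, strain_abs_sd)` noise, standard deviations clipped at 0. The draw
#' is local to `noise$seed`.
#'
#' @param pv clean PV data frame (`t_s`, `p_kPa`, `V_added_mL`).
#' @param strain_stats clean `lobe_strain_stats` table.
#' @param noise a [noise_spec()].
#' @return list with noisy `pv` and `strain_stats`.
#' @export
apply_measurement_noise <- function(pv, strain_stats, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  with_seed(noise$seed, {
    V <- pv$V_added_mL * (1 + rnorm(nrow(pv), sd = noise$pv_rel_sd))
    V[1] <- 0
    m <- strain_stats$mean_strain +
      rnorm(nrow(strain_stats), sd = noise$strain_abs_sd)
    s <- pmax(0, strain_stats$std_strain +
                rnorm(nrow(strain_stats), sd = noise$strain_abs_sd))
    pv$V_added_mL <- V
    strain_stats$mean_strain <- m
    strain_stats$std_strain <- s
    list(pv = pv, strain_stats = strain_stats)
  })
}

#' Generate a synthetic ventilation experiment with known ground truth
#'
#' Runs the forward model at `theta_true`, samples the 20 PV pairs and the
#' 30 lobe strain statistics, applies measurement noise, and records the
#' generating parameters and seeds in the provenance. With zero noise the
#' record reproduces the simulation exactly, so the calibration objective
#' at `theta_true` is identically zero.
#'
#' @param theta_true named parameter vector (default
#'   [default_true_theta()]).
#' @param geom a [lung_geometry()] (default [default_lung_geometry()]).
#' @param ramp a [pressure_ramp()] (default [make_ramp()]).
#' @param noise a [noise_spec()]; use
#'   `noise_spec(0, 0)` for a noiseless record.
#' @param n_patches patches per lobe (default 20).
#' @param lobes_seed seed of the patch permeability multipliers
#'   (default 101).
#' @param n_steps forward integration output intervals (default 100).
#' @param config optional [forward_config()] overriding the fixed model
#'   constants (baseline, airway fraction, heterogeneity sigma, tolerances).
#' @return an [experiment_record()] with synthetic provenance.
#' @export
make_experiment <- function(theta_true = default_true_theta(),
                            geom = default_lung_geometry(),
                            ramp = make_ramp(),
                            noise = noise_spec(),
                            n_patches = 20L, lobes_seed = 101L,
                            n_steps = 100L,
                            config = forward_config(n_patches = n_patches,
                                                    lobes_seed = lobes_seed,
                                                    n_steps = n_steps)) {
  theta_true <- .check_theta(theta_true)
  mats <- theta_to_materials(theta_true, config$pleura_baseline,
                             config$thickness0, config$airway_fraction,
                             config$heterogeneity_sigma)
  lobes <- build_lobes(geom, mats, config$n_patches,
                       as.integer(config$lobes_seed))
  sim <- simulate_inflation(lobes, mats, ramp, config$n_steps,
                            config$rtol, config$atol)
  pv <- sample_pv(sim, n = 20L)
  stats <- extract_strain_stats(sim)
  noisy <- apply_measurement_noise(pv, stats, noise)
  experiment_record(
    pv = noisy$pv, strain_stats = noisy$strain_stats, geometry = geom,
    ramp = ramp,
    provenance = list(type = "synthetic",
                      theta_true = as.list(theta_true),
                      lobes_seed = as.integer(config$lobes_seed),
                      n_patches = config$n_patches,
                      n_steps = config$n_steps,
                      noise = list(pv_rel_sd = noise$pv_rel_sd,
                                   strain_abs_sd = noise$strain_abs_sd,
                                   seed = noise$seed)))
}

#' Specification of a synthetic pleura equibiaxial dataset
#'
#' Emulates a multi-donor membrane testing campaign: each donor carries a
#' lognormal stiffness multiplier on the shared baseline (the biological
#' spread the lung-specific pleura multiplier compensates for), and each
#' square sample contributes one noisy stress-strain curve. The default
#' campaign size is 9 donors x 12 samples = 108 curves.
#'
#' @param baseline a [reduced_polynomial_params()]
#'   (default [pleura_baseline_default()]).
#' @param n_donors number of donors (default 9).
#' @param samples_per_donor curves per donor (default 12).
#' @param donor_sigma lognormal sigma of the donor multipliers
#'   (default 0.5).
#' @param noise_sd_kPa additive stress noise (default 0.5 kPa).
#' @param strain_max maximum nominal strain of the grid (default 0.6).
#' @param n_points strain points per curve (default 25).
#' @param seed integer seed.
#' @return a list of class `biaxial_spec`.
#' @export
biaxial_spec <- function(baseline = pleura_baseline_default(),
                         n_donors = 9L, samples_per_donor = 12L,
                         donor_sigma = 0.5, noise_sd_kPa = 0.5,
                         strain_max = 0.6, n_points = 25L, seed = 7L) {
  stopifnot(inherits(baseline, "reduced_polynomial_params"),
            n_donors >= 1, samples_per_donor >= 1, donor_sigma >= 0,
            noise_sd_kPa >= 0, strain_max > 0, n_points >= 2)
  structure(list(baseline = baseline, n_donors = as.integer(n_donors),
                 samples_per_donor = as.integer(samples_per_donor),
                 donor_sigma = donor_sigma, noise_sd_kPa = noise_sd_kPa,
                 strain_max = strain_max, n_points = as.integer(n_points),
                 seed = as.integer(seed)), class = "biaxial_spec")
}

#' Generate a synthetic pleura equibiaxial dataset
#'
#' @param spec a [biaxial_spec()].
#' @return list with `data` (data frame: `sample_id`, `donor_id`,
#'   `nominal_strain`, `nominal_stress_kPa`) and `truth` (baseline, donor
#'   multipliers, seed).
#' @export
make_biaxial <- function(spec = biaxial_spec()) {
  stopifnot(inherits(spec, "biaxial_spec"))
  strain <- seq(0, spec$strain_max, length.out = spec$n_points)
  lam <- 1 + strain
  with_seed(spec$seed, {
    mult <- exp(rnorm(spec$n_donors, mean = 0, sd = spec$donor_sigma))
    rows <- list()
    for (d in seq_len(spec$n_donors)) {
      donor_rp <- reduced_polynomial_params(
        spec$baseline$coefficients * mult[d])
      clean <- equibiaxial_nominal_stress(donor_rp, lam)
      for (s in seq_len(spec$samples_per_donor)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("d%02d_s%02d", d, s),
          donor_id = d,
          nominal_strain = strain,
          nominal_stress_kPa = clean +
            rnorm(length(lam), sd = spec$noise_sd_kPa),
          stringsAsFactors = FALSE)
      }
    }
    list(data = do.call(rbind, rows),
         truth = list(baseline = spec$baseline, donor_multipliers = mult,
                      seed = spec$seed))
  })
}
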