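# File interchange. An experiment record is a directory with pv.csv,
# strain_stats.csv and meta.json; materials serialise to JSON with
# unit-annotated key names. CSV + JSON is deliberate: there is no standard
# bioformat for PV/strain-statistic ventilation records.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Write an experiment record to a directory
#'
#' Creates `pv.csv` (`t_s`, `p_kPa`, `V_added_mL`), `strain_stats.csv`
#' (`lobe`, `stage_fraction`, `mean_strain`, `std_strain`) and `meta.json`
#' (geometry scalars, ramp tabulation, provenance). The round trip through
#' [read_experiment()] is lossless.
#'
#' @param record an [experiment_record()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(record, dir) {
  stopifnot(inherits(record, "experiment_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(record$pv, file.path(dir, "pv.csv"), row.names = FALSE)
  ss <- record$strain_stats
  ss$lobe <- as.character(ss$lobe)
  write.csv(ss, file.path(dir, "strain_stats.csv"), row.names = FALSE)
  g <- record$geometry
  meta <- list(
    geometry = list(V_total_mL = g$V_total_mL, m_lung_g = g$m_lung_g,
                    rho_lung_g_cm3 = g$rho_lung_g_cm3,
                    lobe_fractions = as.list(g$lobe_fractions)),
    ramp = list(times_s = record$ramp$times,
                pressures_kPa = record$ramp$pressures,
                shape = record$ramp$shape),
    provenance = record$provenance
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment record from a directory
#'
#' Validates the column layout, the 20-pair PV count, the 15-row (30
#' statistic) strain table, the zeroed first volume and the presence of
#' provenance, then rebuilds the [experiment_record()].
#'
#' @param dir directory written by [write_experiment()].
#' @return an [experiment_record()].
#' @export
read_experiment <- function(dir) {
  for (f in c("pv.csv", "strain_stats.csv", "meta.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop(sprintf("experiment directory is missing %s", f), call. = FALSE)
    }
  }
  pv <- read.csv(file.path(dir, "pv.csv"))
  .require_columns(pv, c("t_s", "p_kPa", "V_added_mL"), "pv.csv")
  if (nrow(pv) != 20) {
    stop(sprintf(
      "pv.csv must contain exactly 20 pressure/volume pairs (found %d)",
      nrow(pv)), call. = FALSE)
  }
  ss <- read.csv(file.path(dir, "strain_stats.csv"))
  .require_columns(ss, c("lobe", "stage_fraction", "mean_strain",
                         "std_strain"), "strain_stats.csv")
  if (nrow(ss) != 15) {
    stop(sprintf(
      "strain_stats.csv must contain 15 rows = 30 statistics (found %d)",
      nrow(ss)), call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$provenance) || is.null(meta$provenance$type)) {
    stop("meta.json must carry a provenance block with a type",
         call. = FALSE)
  }
  geom <- lung_geometry(meta$geometry$V_total_mL, meta$geometry$m_lung_g,
                        meta$geometry$rho_lung_g_cm3,
                        unlist(meta$geometry$lobe_fractions))
  ramp <- pressure_ramp(meta$ramp$times_s, meta$ramp$pressures_kPa,
                        shape = meta$ramp$shape)
  experiment_record(pv, ss, geom, ramp, meta$provenance)
}

#' Export a forward result as CSV files
#'
#' Writes `pv.csv` (the full time history `t_s`, `p_kPa`, `V_added_mL`) and
#' `strain_stats.csv` (the 15 lobe/stage rows).
#'
#' @param result a [simulate_inflation()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_forward_result <- function(result, dir) {
  stopifnot(inherits(result, "forward_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(t_s = result$times, p_kPa = result$p_tr,
                       V_added_mL = result$V_added_mL),
            file.path(dir, "pv.csv"), row.names = FALSE)
  ss <- extract_strain_stats(result)
  ss$lobe <- as.character(ss$lobe)
  write.csv(ss, file.path(dir, "strain_stats.csv"), row.names = FALSE)
  invisible(dir)
}

#' Serialise a material set to JSON
#'
#' Keys carry explicit unit annotations: `mu_kPa`, `alpha`, `nu`,
#' `k_per_lobe_1e3_mm2_per_s`, `C10_kPa`, `pleura_lambda`,
#' `pleura_baseline_kPa`, `pleura_thickness0_mm`, `airway_fraction`,
#' `heterogeneity_sigma`.
#'
#' @param mats a [material_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_materials_json <- function(mats, path) {
  stopifnot(inherits(mats, "material_set"))
  obj <- list(
    mu_kPa = mats$parenchyma$mu,
    alpha = mats$parenchyma$alpha,
    nu = mats$parenchyma$nu,
    k_per_lobe_1e3_mm2_per_s = as.list(mats$permeabilities),
    C10_kPa = mats$airways$C10,
    D_per_kPa = mats$airways$D,
    pleura_lambda = mats$pleura$scale_lambda,
    pleura_baseline_kPa = mats$pleura$baseline$coefficients,
    pleura_thickness0_mm = mats$pleura$thickness0,
    airway_fraction = mats$airway_fraction,
    heterogeneity_sigma = mats$heterogeneity_sigma
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a material set from JSON
#'
#' @param path file written by [write_materials_json()].
#' @return a [material_set()].
#' @export
read_materials_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("mu_kPa", "alpha", "nu", "k_per_lobe_1e3_mm2_per_s",
              "C10_kPa", "pleura_lambda", "pleura_baseline_kPa")
  missing <- setdiff(needed, names(obj))
  if (length(missing)) {
    stop("materials JSON is missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  material_set(
    parenchyma = hyperfoam_params(obj$mu_kPa, obj$alpha, obj$nu),
    permeabilities = unlist(obj$k_per_lobe_1e3_mm2_per_s),
    airways = neo_hookean_params(obj$C10_kPa,
                                 if (is.null(obj$D_per_kPa)) 0 else
                                   obj$D_per_kPa),
    pleura = pleura_material(
      reduced_polynomial_params(unlist(obj$pleura_baseline_kPa)),
      obj$pleura_lambda,
      if (is.null(obj$pleura_thickness0_mm)) 0.06 else
        obj$pleura_thickness0_mm),
    airway_fraction = if (is.null(obj$airway_fraction)) 0.02 else
      obj$airway_fraction,
    heterogeneity_sigma = if (is.null(obj$heterogeneity_sigma)) 0.3 else
      obj$heterogeneity_sigma
  )
}
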