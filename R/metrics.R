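# Calibration targets and mismatch metrics: the experiment record (20 PV
# pairs + 30 lobe strain statistics), the relative-error breakdown used for
# ranking solutions, and the 50-component normalised residual vector whose
# squared norm is the calibration objective.

#' Experiment record: the calibration target
#'
#' @param pv data frame with exactly 20 rows and columns `t_s`, `p_kPa`,
#'   `V_added_mL`; the first volume must be 0 (volumes are zeroed at the
#'   start of inflation).
#' @param strain_stats a 15-row data frame with columns `lobe`,
#'   `stage_fraction`, `mean_strain`, `std_strain` (5 lobes x 3 stages,
#'   i.e. 30 strain statistics).
#' @param geometry a [lung_geometry()] object (bookkeeping scalars).
#' @param ramp the [pressure_ramp()] that produced the record.
#' @param provenance a list with at least `type` ("measured" or
#'   "synthetic"); synthetic records carry `theta_true`, `lobes_seed`,
#'   `n_patches`, `n_steps` and the noise specification.
#' @return an object of class `experiment_record`.
#' @export
experiment_record <- function(pv, strain_stats, geometry, ramp, provenance) {
  stopifnot(is.data.frame(pv), is.data.frame(strain_stats),
            inherits(geometry, "lung_geometry"),
            inherits(ramp, "pressure_ramp"), is.list(provenance))
  if (!all(c("t_s", "p_kPa", "V_added_mL") %in% names(pv))) {
    stop("`pv` needs columns t_s, p_kPa, V_added_mL", call. = FALSE)
  }
  if (nrow(pv) != 20) {
    stop(sprintf("`pv` must have exactly 20 pressure/volume pairs (got %d)",
                 nrow(pv)), call. = FALSE)
  }
  if (abs(pv$V_added_mL[1]) > 1e-9) {
    stop("first PV volume must be 0 (added volume is zeroed at t = 0)",
         call. = FALSE)
  }
  needed <- c("lobe", "stage_fraction", "mean_strain", "std_strain")
  if (!all(needed %in% names(strain_stats))) {
    stop("`strain_stats` needs columns lobe, stage_fraction, mean_strain, ",
         "std_strain", call. = FALSE)
  }
  if (nrow(strain_stats) != 15) {
    stop(sprintf(
      "`strain_stats` must have 15 rows = 30 strain statistics (got %d)",
      nrow(strain_stats)), call. = FALSE)
  }
  if (any(strain_stats$std_strain < 0)) {
    stop("strain standard deviations must be >= 0", call. = FALSE)
  }
  if (is.null(provenance$type) ||
      !provenance$type %in% c("measured", "synthetic")) {
    stop("`provenance$type` must be 'measured' or 'synthetic'", call. = FALSE)
  }
  strain_stats <- .canonical_stats(strain_stats)
  structure(list(pv = pv, strain_stats = strain_stats, geometry = geometry,
                 ramp = ramp, provenance = provenance),
            class = "experiment_record")
}

# Reorder strain statistics into the canonical lobe-major, stage-minor
# order so residual components always align.
.canonical_stats <- function(stats) {
  stats$lobe <- factor(as.character(stats$lobe), levels = LOBE_NAMES)
  if (anyNA(stats$lobe)) stop("unknown lobe label", call. = FALSE)
  key <- paste(stats$lobe, format(stats$stage_fraction))
  want <- paste(factor(rep(LOBE_NAMES, each = 3), levels = LOBE_NAMES),
                format(rep(STAGE_FRACTIONS, 5)))
  idx <- match(want, key)
  if (anyNA(idx)) {
    stop("strain_stats must contain each lobe at stages 0.3, 0.6, 1.0",
         call. = FALSE)
  }
  out <- stats[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pointwise and mean relative volume error (percent)
#'
#' `100 * |V_exp - V_num| / V_exp` per point. Points with `V_exp = 0` (the
#' zeroed start of inflation) are excluded from the mean and reported as
#' `NA` in the pointwise series.
#'
#' @param V_exp,V_num experimental and model volume series (mL), equal
#'   length.
#' @return list with `per_point` (percent, `NA` where `V_exp = 0`) and
#'   `mean`.
#' @export
relative_volume_error <- function(V_exp, V_num) {
  if (length(V_exp) != length(V_num)) {
    stop("volume series must have equal length", call. = FALSE)
  }
  per <- ifelse(V_exp == 0, NA_real_, 100 * abs(V_exp - V_num) / V_exp)
  list(per_point = per, mean = mean(per, na.rm = TRUE))
}

#' Relative strain-statistic errors (percent)
#'
#' The volume error formula applied to each of the 15 lobe/stage mean
#' strains and 15 standard deviations. Components whose experimental value
#' is zero are excluded from the block aggregates.
#'
#' @param exp_stats,num_stats `lobe_strain_stats` data frames with matching
#'   lobe/stage layout.
#' @return list with `mean_per_point`, `std_per_point` (percent) and the
#'   block aggregates `mean_error`, `std_error`.
#' @export
strain_errors <- function(exp_stats, num_stats) {
  e <- .canonical_stats(exp_stats)
  n <- .canonical_stats(num_stats)
  if (nrow(e) != nrow(n)) stop("shape mismatch", call. = FALSE)
  rel <- function(x, y) ifelse(x == 0, NA_real_, 100 * abs(x - y) / abs(x))
  mp <- rel(e$mean_strain, n$mean_strain)
  sp <- rel(e$std_strain, n$std_strain)
  list(mean_per_point = mp, std_per_point = sp,
       mean_error = mean(mp, na.rm = TRUE),
       std_error = mean(sp, na.rm = TRUE))
}

#' Error breakdown of a simulation against an experiment
#'
#' The three-block triplet used to rank calibration solutions: mean
#' relative error of the 20 volumes, of the 15 lobe mean strains and of the
#' 15 strain standard deviations, all in percent.
#'
#' @param exp an [experiment_record()].
#' @param sim a [simulate_inflation()] result on the experiment's ramp.
#' @return an object of class `error_breakdown`: list with `volume_pct`,
#'   `mean_strain_pct`, `std_strain_pct`.
#' @export
error_breakdown <- function(exp, sim) {
  stopifnot(inherits(exp, "experiment_record"),
            inherits(sim, "forward_result"))
  pv_num <- sample_pv(sim, n = nrow(exp$pv))
  se <- strain_errors(exp$strain_stats, extract_strain_stats(sim))
  structure(list(
    volume_pct = relative_volume_error(exp$pv$V_added_mL,
                                       pv_num$V_added_mL)$mean,
    mean_strain_pct = se$mean_error,
    std_strain_pct = se$std_error
  ), class = "error_breakdown")
}

#' Normalised residual vector of a simulation against an experiment
#'
#' The 50 ordered components behind the calibration objective: 20 volume
#' residuals, 15 mean-strain residuals, 15 std-strain residuals, each
#' difference divided by its block normaliser — the standard deviation of
#' the corresponding experimental values (`delta_V`, `delta_xbar`,
#' `delta_sigma`). The objective is `phi = sum(residuals^2)`.
#'
#' @param exp an [experiment_record()].
#' @param sim a [simulate_inflation()] result on the experiment's ramp.
#' @return numeric(50) with attributes `block` (component labels),
#'   `normalizers` and `phi`.
#' @export
residual_vector <- function(exp, sim) {
  stopifnot(inherits(exp, "experiment_record"),
            inherits(sim, "forward_result"))
  pv_num <- sample_pv(sim, n = nrow(exp$pv))
  num_stats <- .canonical_stats(extract_strain_stats(sim))
  exp_stats <- exp$strain_stats
  d_V <- sd(exp$pv$V_added_mL)
  d_m <- sd(exp_stats$mean_strain)
  d_s <- sd(exp_stats$std_strain)
  if (!all(is.finite(c(d_V, d_m, d_s))) || any(c(d_V, d_m, d_s) == 0)) {
    stop("degenerate experiment: a block normaliser is zero", call. = FALSE)
  }
  r <- c((exp$pv$V_added_mL - pv_num$V_added_mL) / d_V,
         (exp_stats$mean_strain - num_stats$mean_strain) / d_m,
         (exp_stats$std_strain - num_stats$std_strain) / d_s)
  if (any(!is.finite(r))) {
    stop("non-finite residuals (forward model produced invalid output)",
         call. = FALSE)
  }
  attr(r, "block") <- rep(c("volume", "mean_strain", "std_strain"),
                          c(20, 15, 15))
  attr(r, "normalizers") <- c(delta_V = d_V, delta_xbar = d_m,
                              delta_sigma = d_s)
  attr(r, "phi") <- sum(r^2)
  r
}

#' @export
print.error_breakdown <- function(x, ...) {
  cat(sprintf(
    "Errors: volume %.2f%%, mean strain %.2f%%, strain std %.2f%%\n",
    x$volume_pct, x$mean_strain_pct, x$std_strain_pct))
  invisible(x)
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf(
    "Experiment record (%s): %d PV pairs to %.3g kPa, %d strain statistics\n",
    x$provenance$type, nrow(x$pv), x$ramp$p_max, 2 * nrow(x$strain_stats)))
  invisible(x)
}
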