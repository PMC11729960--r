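# Lung volume bookkeeping: submersion-test total volume, tissue volume from
# mass and density, initial air volume and porosity, lobe volume fractions.

#' Initial air volume and porosity from bookkeeping scalars
#'
#' `V_tissue = m_lung / rho_lung`, `V_air0 = V_total - V_tissue`,
#' `porosity0 = V_air0 / V_total` (fully saturated medium assumed).
#'
#' @param m_lung_g tissue mass (g).
#' @param rho_lung_g_cm3 tissue density (g/cm^3); deflated lung tissue is
#'   close to 1.0.
#' @param V_total_mL total organ volume from a submersion test (mL).
#' @return list with `V_tissue_mL`, `V_air0_mL`, `porosity0`.
#' @export
#' @examples
#' initial_volumes(818, 1.0, 2430)  # 1612 mL of air, porosity ~0.66
initial_volumes <- function(m_lung_g, rho_lung_g_cm3, V_total_mL) {
  stopifnot(is.numeric(m_lung_g), is.numeric(rho_lung_g_cm3),
            is.numeric(V_total_mL))
  if (m_lung_g <= 0 || rho_lung_g_cm3 <= 0 || V_total_mL <= 0) {
    stop("all bookkeeping scalars must be positive", call. = FALSE)
  }
  V_tissue <- m_lung_g / rho_lung_g_cm3
  V_air0 <- V_total_mL - V_tissue
  if (V_air0 <= 0) {
    stop("inconsistent volumes: V_total must exceed V_tissue ",
         "(porosity must satisfy 0 < phi < 1)", call. = FALSE)
  }
  list(V_tissue_mL = V_tissue, V_air0_mL = V_air0,
       porosity0 = V_air0 / V_total_mL)
}

#' Five-lobe lung geometry
#'
#' @param V_total_mL total organ volume (mL).
#' @param m_lung_g tissue mass (g).
#' @param rho_lung_g_cm3 tissue density (g/cm^3), default 1.0.
#' @param lobe_fractions five nonnegative volume fractions in the order
#'   UL, LL, UR, MR, LR, summing to 1. The defaults are plumbing (lobe
#'   fractions are not part of the experimental record), configurable.
#' @return an object of class `lung_geometry` with derived `V_tissue_mL`,
#'   `V_air0_mL`, `porosity0` and per-lobe initial volumes `V_lobes_mL`.
#' @export
lung_geometry <- function(V_total_mL, m_lung_g, rho_lung_g_cm3 = 1.0,
                          lobe_fractions = c(UL = 0.20, LL = 0.25, UR = 0.20,
                                             MR = 0.10, LR = 0.25)) {
  vols <- initial_volumes(m_lung_g, rho_lung_g_cm3, V_total_mL)
  lobe_fractions <- as.numeric(lobe_fractions)
  if (length(lobe_fractions) != 5 || any(lobe_fractions < 0)) {
    stop("`lobe_fractions` must be five nonnegative values", call. = FALSE)
  }
  if (abs(sum(lobe_fractions) - 1) > 1e-12) {
    stop("`lobe_fractions` must sum to 1 (within 1e-12)", call. = FALSE)
  }
  names(lobe_fractions) <- LOBE_NAMES
  structure(list(
    V_total_mL = V_total_mL,
    m_lung_g = m_lung_g,
    rho_lung_g_cm3 = rho_lung_g_cm3,
    lobe_fractions = lobe_fractions,
    V_lobes_mL = lobe_fractions * V_total_mL,
    V_tissue_mL = vols$V_tissue_mL,
    V_air0_mL = vols$V_air0_mL,
    porosity0 = vols$porosity0
  ), class = "lung_geometry")
}

#' Default study geometry
#'
#' The donor bookkeeping scalars used throughout the synthetic fixtures:
#' 2430 mL submersion volume, 818 g tissue at density 1.0 g/cm^3.
#'
#' @return a [lung_geometry()] object.
#' @export
default_lung_geometry <- function() {
  lung_geometry(V_total_mL = 2430, m_lung_g = 818, rho_lung_g_cm3 = 1.0)
}

#' Rescale a lung geometry to a target total volume
#'
#' Mimics scaling the whole mesh: every lobe volume is multiplied by
#' `V_total_target / V_total`; fractions and porosity are unchanged (tissue
#' mass scales with the same ratio).
#'
#' @param geom a [lung_geometry()] object.
#' @param V_total_target_mL target total volume (mL), `> 0`.
#' @return a new `lung_geometry`.
#' @export
scale_model_volume <- function(geom, V_total_target_mL) {
  stopifnot(inherits(geom, "lung_geometry"))
  if (!is.numeric(V_total_target_mL) || V_total_target_mL <= 0) {
    stop("target volume must be > 0", call. = FALSE)
  }
  ratio <- V_total_target_mL / geom$V_total_mL
  lung_geometry(V_total_target_mL, geom$m_lung_g * ratio,
                geom$rho_lung_g_cm3, geom$lobe_fractions)
}

#' @export
print.lung_geometry <- function(x, ...) {
  cat(sprintf(
    "Lung geometry: V_total = %g mL, V_tissue = %g mL, V_air0 = %g mL (porosity %.1f%%)\n",
    x$V_total_mL, x$V_tissue_mL, x$V_air0_mL, 100 * x$porosity0))
  cat("  lobe fractions:",
      paste(sprintf("%s %.2f", LOBE_NAMES, x$lobe_fractions), collapse = ", "),
      "\n")
  invisible(x)
}
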