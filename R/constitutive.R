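# Strain-energy functions, stresses and parameter conversions for the three
# lung constituents: compressible Ogden hyperfoam (parenchyma), Neo-Hookean
# (airways), reduced polynomial (pleura membrane). Stresses are Cauchy
# internally; the equibiaxial membrane response is exposed as nominal
# (first Piola) stress because biaxial rigs report nominal stress-strain.

#' Convert a Poisson's ratio to the hyperfoam volumetric exponent
#'
#' The compressible foam energy couples its volumetric and deviatoric parts
#' through `beta = nu / (1 - 2 nu)`. `beta` diverges at the incompressible
#' limit, so `nu = 0.5` is rejected.
#'
#' @param nu Poisson's ratio, `0 <= nu < 0.5`. Vectorised.
#' @return `nu / (1 - 2 * nu)`, nonnegative on the admissible domain.
#' @export
#' @examples
#' poisson_ratio_to_beta(c(0, 0.25, 0.4))
poisson_ratio_to_beta <- function(nu) {
  if (!is.numeric(nu) || any(!is.finite(nu))) {
    stop("`nu` must be finite numeric", call. = FALSE)
  }
  if (any(nu < 0) || any(nu >= 0.5)) {
    stop("`nu` must satisfy 0 <= nu < 0.5 (beta diverges as nu -> 0.5)",
         call. = FALSE)
  }
  nu / (1 - 2 * nu)
}

#' Hyperfoam (Ogden foam) material parameters
#'
#' One-term compressible foam in principal stretches with initial shear
#' modulus `mu`, stretch exponent `alpha` and Poisson's ratio `nu`.
#'
#' @param mu initial shear modulus (kPa), `> 0`.
#' @param alpha dimensionless stretch exponent, nonzero.
#' @param nu Poisson's ratio, `0 <= nu < 0.5`.
#' @return an object of class `hyperfoam_params`.
#' @export
hyperfoam_params <- function(mu, alpha, nu) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.numeric(alpha),
            length(alpha) == 1, is.numeric(nu), length(nu) == 1)
  if (!is.finite(mu) || mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (!is.finite(alpha) || alpha == 0) {
    stop("`alpha` must be nonzero", call. = FALSE)
  }
  beta <- poisson_ratio_to_beta(nu)
  structure(list(mu = mu, alpha = alpha, nu = nu, beta = beta),
            class = c("hyperfoam_params", "porolung_material"))
}

#' Neo-Hookean material parameters
#'
#' `D = 0` (the default) means incompressibility is enforced analytically:
#' responses are evaluated on isochoric paths only and no volumetric penalty
#' term is ever formed.
#'
#' @param C10 stiffness coefficient (kPa), `> 0`. Initial shear modulus is
#'   `2 * C10`.
#' @param D compressibility parameter (1/kPa), `>= 0`.
#' @return an object of class `neo_hookean_params`.
#' @export
neo_hookean_params <- function(C10, D = 0) {
  stopifnot(is.numeric(C10), length(C10) == 1, is.numeric(D), length(D) == 1)
  if (!is.finite(C10) || C10 <= 0) stop("`C10` must be > 0", call. = FALSE)
  if (!is.finite(D) || D < 0) stop("`D` must be >= 0", call. = FALSE)
  structure(list(C10 = C10, D = D),
            class = c("neo_hookean_params", "porolung_material"))
}

#' Reduced-polynomial hyperelastic parameters
#'
#' Energy `U = sum_i C_i0 * (I1bar - 3)^i`, depending only on the first
#' deviatoric invariant. The first coefficient sets the initial shear
#' modulus `2 * C10`.
#'
#' @param coefficients ordered numeric vector `C_10, C_20, ...` (kPa);
#'   at least one term, first term `> 0`.
#' @return an object of class `reduced_polynomial_params`.
#' @export
reduced_polynomial_params <- function(coefficients) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1 || any(!is.finite(coefficients))) {
    stop("`coefficients` must be a nonempty finite numeric vector",
         call. = FALSE)
  }
  if (coefficients[1] <= 0) {
    stop("first coefficient C10 must be > 0 (it sets the shear modulus)",
         call. = FALSE)
  }
  structure(list(coefficients = coefficients, order = length(coefficients)),
            class = c("reduced_polynomial_params", "porolung_material"))
}

#' Pleura membrane material
#'
#' A reduced-polynomial baseline (fitted once to pooled equibiaxial data)
#' with a dimensionless multiplier `scale_lambda` applied to every
#' coefficient, adapting the lung-specific stiffness while preserving the
#' bilinear shape of the stress-strain curve, plus a reference thickness.
#'
#' @param baseline a [reduced_polynomial_params()] object.
#' @param scale_lambda coefficient multiplier, in `[1e-6, 3]`.
#' @param thickness0 reference membrane thickness (mm), default 0.06.
#' @return an object of class `pleura_material`.
#' @export
pleura_material <- function(baseline, scale_lambda = 1, thickness0 = 0.06) {
  stopifnot(inherits(baseline, "reduced_polynomial_params"),
            is.numeric(scale_lambda), length(scale_lambda) == 1,
            is.numeric(thickness0), length(thickness0) == 1)
  if (!is.finite(scale_lambda) || scale_lambda < 1e-6 || scale_lambda > 3) {
    stop("`scale_lambda` must lie in [1e-6, 3]", call. = FALSE)
  }
  if (!is.finite(thickness0) || thickness0 <= 0) {
    stop("`thickness0` must be > 0", call. = FALSE)
  }
  structure(list(baseline = baseline, scale_lambda = scale_lambda,
                 thickness0 = thickness0),
            class = c("pleura_material", "porolung_material"))
}

#' Default pleura baseline coefficients
#'
#' Two-term reduced polynomial with `2 * C10 = 2.4` kPa and a stiffening
#' quadratic term, reproducing the bilinear equibiaxial response of pleural
#' membrane tissue (soft below ~30% strain, steeply stiffening beyond).
#'
#' @return a [reduced_polynomial_params()] object, coefficients (1.2, 6) kPa.
#' @export
pleura_baseline_default <- function() {
  reduced_polynomial_params(c(1.2, 6.0))
}

.check_stretches <- function(stretches) {
  if (!is.numeric(stretches) || length(stretches) != 3 ||
      any(!is.finite(stretches)) || any(stretches <= 0)) {
    stop("`stretches` must be three finite positive principal stretches",
         call. = FALSE)
  }
  stretches
}

# Threshold below which the volumetric term switches to its analytic
# beta -> 0 limit (-alpha * log J); naive evaluation divides by beta.
.BETA_EPS <- 1e-10

#' Hyperfoam strain-energy density
#'
#' `U = (2 mu / alpha^2) * (l1^a + l2^a + l3^a - 3 + (1/beta)(J^(-a b) - 1))`
#' with `J = l1 l2 l3`. At `nu = 0` (`beta = 0`) the volumetric term is its
#' analytic limit `-alpha * log(J)`. `U` vanishes in the reference state.
#'
#' @param p a [hyperfoam_params()] object.
#' @param stretches numeric(3) principal stretches, all `> 0`.
#' @return energy density (kPa).
#' @export
hyperfoam_energy <- function(p, stretches) {
  stopifnot(inherits(p, "hyperfoam_params"))
  l <- .check_stretches(stretches)
  J <- prod(l)
  a <- p$alpha
  vol <- if (abs(p$beta) < .BETA_EPS) {
    -a * log(J)
  } else {
    (J^(-a * p$beta) - 1) / p$beta
  }
  (2 * p$mu / a^2) * (sum(l^a) - 3 + vol)
}

#' Hyperfoam principal Cauchy stresses
#'
#' Closed form `sigma_i = (2 mu / (alpha J)) * (l_i^alpha - J^(-alpha beta))`,
#' i.e. `sigma_i = (l_i / J) * dU/dl_i`. Zero at the identity.
#'
#' @inheritParams hyperfoam_energy
#' @return numeric(3) principal Cauchy stresses (kPa).
#' @export
hyperfoam_principal_stress <- function(p, stretches) {
  stopifnot(inherits(p, "hyperfoam_params"))
  l <- .check_stretches(stretches)
  J <- prod(l)
  (2 * p$mu / (p$alpha * J)) * (l^p$alpha - J^(-p$alpha * p$beta))
}

#' Apply the pleura stiffness multiplier to its baseline coefficients
#'
#' Every baseline coefficient is multiplied by `scale_lambda`
#' (`C_i0* = lambda * C_i0`); the polynomial order is preserved.
#'
#' @param m a [pleura_material()] object.
#' @return a [reduced_polynomial_params()] object with scaled coefficients.
#' @export
scale_reduced_polynomial <- function(m) {
  stopifnot(inherits(m, "pleura_material"))
  reduced_polynomial_params(m$baseline$coefficients * m$scale_lambda)
}

#' Initial shear modulus of a material
#'
#' Hyperfoam returns `mu`; Neo-Hookean and reduced polynomial return
#' `2 * C10`; a pleura material returns `2 * scale_lambda * C10` of its
#' baseline (the scaled modulus).
#'
#' @param material a material object from this package.
#' @return initial shear modulus (kPa).
#' @export
initial_shear_modulus <- function(material) {
  UseMethod("initial_shear_modulus")
}

#' @export
initial_shear_modulus.hyperfoam_params <- function(material) material$mu

#' @export
initial_shear_modulus.neo_hookean_params <- function(material) {
  2 * material$C10
}

#' @export
initial_shear_modulus.reduced_polynomial_params <- function(material) {
  2 * material$coefficients[1]
}

#' @export
initial_shear_modulus.pleura_material <- function(material) {
  2 * material$scale_lambda * material$baseline$coefficients[1]
}

#' Equibiaxial nominal stress of a reduced-polynomial membrane
#'
#' Incompressible equibiaxial kinematics `l1 = l2 = lam`, `l3 = lam^-2`,
#' `I1bar = 2 lam^2 + lam^-4`. The nominal (first Piola) stress per loading
#' direction is
#' `P(lam) = 2 (lam - lam^-5) * sum_i i C_i0 (I1bar - 3)^(i-1)`,
#' which for one term reduces to the Neo-Hookean `2 C10 (lam - lam^-5)`.
#'
#' @param rp a [reduced_polynomial_params()] object.
#' @param lam in-plane stretch(es), `> 0`. Vectorised.
#' @return nominal stress (kPa), same length as `lam`.
#' @export
equibiaxial_nominal_stress <- function(rp, lam) {
  stopifnot(inherits(rp, "reduced_polynomial_params"))
  if (!is.numeric(lam) || any(!is.finite(lam)) || any(lam <= 0)) {
    stop("`lam` must be finite and > 0", call. = FALSE)
  }
  i1m3 <- 2 * lam^2 + lam^(-4) - 3
  dUdI1 <- rep(0, length(lam))
  for (i in seq_along(rp$coefficients)) {
    dUdI1 <- dUdI1 + i * rp$coefficients[i] * i1m3^(i - 1)
  }
  2 * (lam - lam^(-5)) * dUdI1
}

#' Fit a reduced polynomial to equibiaxial stress-strain curves
#'
#' Pools all points of all sample curves (the pooled least-squares target is
#' the "averaged curve"), converts nominal strain to stretch `lam = 1 + eps`,
#' and solves the linear least-squares problem for the coefficients `C_i0`
#' of [equibiaxial_nominal_stress()]. Deterministic.
#'
#' @param curves a data frame with columns `nominal_strain` and
#'   `nominal_stress_kPa` (a `sample_id` column is allowed and ignored), or a
#'   list of such data frames which are pooled.
#' @param order polynomial order `n >= 1` (default 2).
#' @return a [reduced_polynomial_params()] object; the residual sum of
#'   squares is attached as attribute `rss`.
#' @export
fit_reduced_polynomial <- function(curves, order = 2L) {
  if (is.data.frame(curves)) curves <- list(curves)
  stopifnot(length(curves) >= 1, order >= 1)
  pooled <- do.call(rbind, lapply(curves, function(d) {
    if (!all(c("nominal_strain", "nominal_stress_kPa") %in% names(d))) {
      stop("curves need columns nominal_strain, nominal_stress_kPa",
           call. = FALSE)
    }
    d[, c("nominal_strain", "nominal_stress_kPa")]
  }))
  if (any(!is.finite(pooled$nominal_stress_kPa)) ||
      any(!is.finite(pooled$nominal_strain)) ||
      any(pooled$nominal_strain < 0)) {
    stop("strains must be >= 0 and stresses finite", call. = FALSE)
  }
  if (nrow(pooled) < order) {
    stop(sprintf("ill-posed fit: %d points for %d coefficients",
                 nrow(pooled), order), call. = FALSE)
  }
  lam <- 1 + pooled$nominal_strain
  i1m3 <- 2 * lam^2 + lam^(-4) - 3
  X <- vapply(seq_len(order), function(i) {
    2 * (lam - lam^(-5)) * i * i1m3^(i - 1)
  }, numeric(length(lam)))
  X <- matrix(X, ncol = order)
  fit <- qr(X)
  if (fit$rank < order) {
    stop("ill-posed fit: design matrix is rank deficient", call. = FALSE)
  }
  coefs <- qr.coef(fit, pooled$nominal_stress_kPa)
  out <- reduced_polynomial_params(coefs)
  attr(out, "rss") <- sum((X %*% coefs - pooled$nominal_stress_kPa)^2)
  out
}

# Reduced-polynomial energy as a function of the two in-plane
# Green-Lagrange strains under incompressible kinematics.
.rp_energy_E <- function(rp, E1, E2) {
  l1sq <- 1 + 2 * E1
  l2sq <- 1 + 2 * E2
  i1m3 <- l1sq + l2sq + 1 / (l1sq * l2sq) - 3
  U <- 0
  for (i in seq_along(rp$coefficients)) {
    U <- U + rp$coefficients[i] * i1m3^i
  }
  U
}

#' Check convexity of a reduced polynomial in Green-Lagrange strain
#'
#' Numerically evaluates the 2x2 Hessian of the membrane energy with respect
#' to the in-plane Green-Lagrange strain components over a biaxial stretch
#' grid (incompressible kinematics) and reports whether the minimum
#' eigenvalue stays above `-tol`, with `tol = 1e-9 * max|Hessian|` over the
#' grid.
#'
#' @param rp a [reduced_polynomial_params()] object.
#' @param lam_range stretch range for both in-plane directions, within
#'   `[0.5, 3]`; default `c(0.7, 2)`.
#' @param n_grid grid points per direction (default 50).
#' @return a list with elements `convex` (logical), `min_eigenvalue`,
#'   `worst` (stretch pair at the minimum eigenvalue) and `tol`.
#' @export
check_convexity <- function(rp, lam_range = c(0.7, 2.0), n_grid = 50L) {
  stopifnot(inherits(rp, "reduced_polynomial_params"))
  if (length(lam_range) != 2 || diff(lam_range) <= 0 ||
      lam_range[1] < 0.5 || lam_range[2] > 3) {
    stop("`lam_range` must be increasing and within [0.5, 3]", call. = FALSE)
  }
  if (n_grid < 2) stop("degenerate grid", call. = FALSE)
  lam <- seq(lam_range[1], lam_range[2], length.out = n_grid)
  g <- expand.grid(lam1 = lam, lam2 = lam)
  E1 <- (g$lam1^2 - 1) / 2
  E2 <- (g$lam2^2 - 1) / 2
  h <- 1e-5
  U0 <- .rp_energy_E(rp, E1, E2)
  H11 <- (.rp_energy_E(rp, E1 + h, E2) - 2 * U0 +
            .rp_energy_E(rp, E1 - h, E2)) / h^2
  H22 <- (.rp_energy_E(rp, E1, E2 + h) - 2 * U0 +
            .rp_energy_E(rp, E1, E2 - h)) / h^2
  H12 <- (.rp_energy_E(rp, E1 + h, E2 + h) -
            .rp_energy_E(rp, E1 + h, E2 - h) -
            .rp_energy_E(rp, E1 - h, E2 + h) +
            .rp_energy_E(rp, E1 - h, E2 - h)) / (4 * h^2)
  # eigenvalues of a symmetric 2x2, vectorised over the grid
  tr <- H11 + H22
  disc <- sqrt(pmax(0, (H11 - H22)^2 + 4 * H12^2))
  emin <- (tr - disc) / 2
  worst <- which.min(emin)
  tol <- 1e-9 * max(abs(c(H11, H22, H12)))
  list(convex = min(emin) >= -tol,
       min_eigenvalue = emin[worst],
       worst = c(lam1 = g$lam1[worst], lam2 = g$lam2[worst]),
       tol = tol)
}

#' @export
print.hyperfoam_params <- function(x, ...) {
  cat(sprintf("Hyperfoam: mu = %g kPa, alpha = %g, nu = %g (beta = %g)\n",
              x$mu, x$alpha, x$nu, x$beta))
  invisible(x)
}

#' @export
print.neo_hookean_params <- function(x, ...) {
  cat(sprintf("Neo-Hookean: C10 = %g kPa, D = %g 1/kPa%s\n", x$C10, x$D,
              if (x$D == 0) " (incompressible)" else ""))
  invisible(x)
}

#' @export
print.reduced_polynomial_params <- function(x, ...) {
  cat(sprintf("Reduced polynomial (order %d): C_i0 = %s kPa\n", x$order,
              paste(signif(x$coefficients, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.pleura_material <- function(x, ...) {
  cat(sprintf(
    "Pleura: lambda = %g x baseline [%s] kPa, thickness0 = %g mm\n",
    x$scale_lambda, paste(signif(x$baseline$coefficients, 4), collapse = ", "),
    x$thickness0))
  invisible(x)
}
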