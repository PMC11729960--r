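---
title: "Methods: a reduced-order poroelastic lung inflation model and its inverse calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-order poroelastic lung inflation model and its inverse calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porolung)
```

## The problem

Positive-pressure inflation of an excised lung couples two observables:
the global pressure–volume (PV) relationship, which is characteristically
S-shaped with a lower and an upper inflection point, and the local surface
strains, which are distributed unevenly across the five lobes and within
each lobe. A mechanical model that is to be informative about lung tissue
must reproduce both, and the material parameters that achieve this cannot
be measured directly on the intact organ — they must be inferred by
inverse analysis against ventilation experiments.

`porolung` implements a desk-scale version of this programme: a
reduced-order, five-lobe poroelastic forward model built from the
constitutive laws used in organ-scale pulmonary finite-element work, the
mismatch metrics and normalised residual vector of the calibration
problem, a bounded nonlinear least-squares loop with multistart and an
explicit five-criterion termination protocol, and synthetic-data
generators with known ground truth so that every stage of the pipeline is
testable without access to donor data.

## Constitutive model

Three constituents carry the mechanics.

**Parenchyma** is a compressible Ogden-type hyperfoam in principal
stretches $\lambda_1,\lambda_2,\lambda_3$ with $J=\lambda_1\lambda_2\lambda_3$:

$$U = \frac{2\mu}{\alpha^2}\Big(\lambda_1^\alpha + \lambda_2^\alpha +
\lambda_3^\alpha - 3 + \tfrac{1}{\beta}\big(J^{-\alpha\beta}-1\big)\Big),
\qquad \beta = \frac{\nu}{1-2\nu},$$

where $\mu$ (kPa) is the initial shear modulus, $\alpha$ the stretch
exponent and $\nu$ the Poisson ratio. The principal Cauchy stresses have
the closed form $\sigma_i = \frac{2\mu}{\alpha J}(\lambda_i^\alpha -
J^{-\alpha\beta})$. At $\nu = 0$ the factor $1/\beta$ diverges while the
volumetric term vanishes; `hyperfoam_energy()` switches to the analytic
limit $-\alpha\ln J$ below $|\beta| < 10^{-10}$, and the test suite checks
continuity across the switch. The stress formula needs no branch
($J^{-\alpha\beta}\to 1$).

**Airways** are a Neo-Hookean solid with stiffness $C_{10}$ (kPa) treated
as incompressible: the parameter $D$ is interpreted as "enforce
incompressibility analytically" when zero, so responses are evaluated on
isochoric paths and no volumetric penalty is ever formed.

**Pleura** is an incompressible reduced-polynomial membrane,
$U_{RP} = \sum_i C_{i0}(\bar I_1 - 3)^i$, with a single dimensionless
multiplier $\lambda_{pl}$ applied to every coefficient
($C_{i0}^* = \lambda_{pl} C_{i0}$). The multiplier adapts the membrane
stiffness to a specific lung while preserving the bilinear shape of the
equibiaxial stress–strain curve. Under equibiaxial stretch $\lambda$ with
$\bar I_1 = 2\lambda^2 + \lambda^{-4}$ the nominal stress per loading
direction is

$$P(\lambda) = 2(\lambda - \lambda^{-5})\sum_i i\,C_{i0}(\bar I_1-3)^{i-1},$$

which the tests verify against the numeric derivative of the energy along
the same path.

### The pleura baseline

Only the baseline initial shear modulus $2C_{10} = 2.4$ kPa is available
for membranes of this kind; higher-order coefficients are not published.
The package's baseline is therefore its own choice, fixed once:
$C = (1.2, 6.0)$ kPa. The quadratic term is sized so that the equibiaxial
response is soft below roughly 30 % strain and stiffens steeply beyond
40 % — the bilinear, extension-limiting behaviour observed in pleural
membrane testing. `fit_reduced_polynomial()` recovers such coefficients
from pooled multi-sample curves by linear least squares (fitting the
pooled point cloud rather than a pre-averaged curve; the two coincide for
balanced sampling, and pooling is robust to unequal curve lengths), and
`check_convexity()` verifies numerically that a fitted energy is convex in
the in-plane Green–Lagrange strains over a biaxial stretch grid (default
$50\times50$ over $\lambda \in [0.7, 2]$, tolerance $10^{-9}\,
\max|H|$ on the minimum Hessian eigenvalue).

## The reduced-order forward model

The full organ-scale problem — hundreds of thousands of poroelastic
elements, membrane elements, embedded airway beams, lobe–lobe contact —
is deliberately out of scope. The forward model here preserves the
constitutive laws and the pressure-driven filling physics on a geometry
simple enough to run in fractions of a second:

* Each lobe (UL, LL, UR, MR, LR; volume fractions default
  0.20/0.25/0.20/0.10/0.25 — bookkeeping defaults, not measured values)
  is split into `n_patches` parallel spherical compartments of equal
  initial volume $V_0$ and equivalent radius $r_0 = (3V_0/4\pi)^{1/3}$.
* Each patch fills against its elastic recoil
  $p_{rec}(\lambda) = \sigma_{foam}(\lambda) + f_{aw}\,2C_{10}
  (\lambda-\lambda^{-2}) + 2 t_0 P^*(\lambda)/(r_0\lambda^2)$: the
  isotropic hyperfoam Cauchy stress, a uniaxial Neo-Hookean surrogate for
  the embedded airway tree weighted by the volumetric fraction
  $f_{aw}$ (fixed constant, default 0.02), and a Laplace-law membrane
  term with the scaled pleura stress $P^*$ and reference thickness
  $t_0 = 0.06$ mm.
* The filling law per patch is
  $$\frac{dV}{dt} = 4\pi r_0 \lambda \; k \; \frac{p_{tr}(t) -
  p_{rec}(\lambda)}{p_{ref}}, \qquad \lambda = (V/V_0)^{1/3},$$
  integrated with an adaptive stiff-capable solver (`deSolve::ode`,
  lsoda; defaults rtol $10^{-6}$, atol $10^{-9}$ mL, 100 output
  intervals). The Darcy limit is the default; an optional Forchheimer
  coefficient divides the flux by $1 + \beta_F|q|$.

**Units of the permeability.** The lobe permeabilities are tabulated in
$10^{-3}\,\mathrm{mm^2\,s^{-1}}$, a unit that is not dimensionally closed
against pressure differences in kPa. The model closes the law with two
explicit conventions: the normalisation $p_{ref} = 1$ kPa, so that $k$
keeps its printed numeric scale, and the reading of the conductance
$4\pi r_0\lambda\,k$ in mL/s (with $r_0$ in mm). The second convention is
what places the admissible range $k \in [0.1, 100]$ in the physically
meaningful regime: the low end fills sluggishly on the 2-s ramp, the high
end tracks quasi-static equilibrium. A strictly dimensional
$\mathrm{mm^3/s}$ reading would inflate the lung by milliliters per hour
at any admissible $k$, which is not a lung.

**Heterogeneity.** Within a lobe, each patch's permeability is the lobe
value times a lognormal multiplier (median 1, $\sigma = 0.3$, drawn once
from a recorded seed). This stands in for sub-lobar ventilation
heterogeneity and is what produces the nonzero within-lobe strain spread
that the calibration targets; $\sigma$ is a fixed model constant, not a
calibrated parameter, which keeps the calibration space at the standard
parameter set.

**Outputs.** `sample_pv()` returns 20 pressure/volume pairs at times
uniform over the ramp, with the initial volume zeroed as in the
experiments. `extract_strain_stats()` locates the times at which the
tracheal pressure reaches 30 %, 60 % and 100 % of its peak, takes the
major nominal strain $\lambda - 1$ per patch, and reports per-lobe mean
and population standard deviation: 15 + 15 values, the "30 points of
comparison" of the local calibration. The model's known structural
omissions — no lobe–lobe or lobe–plate contact, no gravity, no
viscoelasticity or anisotropy, no camera-view masking of the strain
field, no deflation — mean that passing tests demonstrate correctness of
the implemented physics and of the inverse machinery, not fidelity to any
individual donor lung.

## Calibration metrics

An experiment record carries exactly 20 PV pairs and 30 strain
statistics. The residual vector stacks, in fixed order, 20 volume
residuals, 15 mean-strain residuals and 15 std-strain residuals, each
difference divided by its block normaliser — the standard deviation of
the corresponding *experimental* values ($\delta_V, \delta_{\bar x},
\delta_\sigma$), computed with the zeroed initial volume included. The
objective is $\varphi = \|r\|^2$. Stacking the three blocks into one
least-squares residual (rather than summing or multiplying block sums) is
the reading consistent with minimising by a least-squares solver; the
three-block decomposition is preserved for reporting. The relative-error
triplet (mean of $100\,|x_{exp}-x_{num}|/|x_{exp}|$ per block, the
zero-volume first point excluded from the mean, absolute values applied)
is used to rank competing local minima.

## The optimisation protocol

`ls_minimize()` is a damped Gauss–Newton (Levenberg–Marquardt) iteration
with box bounds enforced by projection and forward-difference Jacobians
with per-parameter steps of $10^{-6}\times$ the bound width. Any
bound-constrained least-squares engine could sit here; the reason the
loop is written explicitly is the termination protocol, which is checked
after every accepted iteration in a fixed order and whose thresholds are
part of the method:

1. function tolerance $|\varphi_i - \varphi_{i+1}| <
   10^{-6}(1+|\varphi_i|)$;
2. more than $100\times$ 9 $=$ 900 function evaluations (the protocol
   counts nine parameters; the vector as tabulated has ten entries —
   $\mu,\alpha,\nu$, five permeabilities, $C_{10}$, $\lambda_{pl}$ — and
   the package keeps the printed cap of 900 as the default rather than
   silently re-deriving 1000);
3. more than 400 iterations;
4. first-order optimality $\max_i |v_i g_i| < 10^{-6}$, where $v_i$ is
   the distance to the bound the negative gradient points toward and 1
   otherwise — the bound-scaled measure used by reflective trust-region
   solvers, so that a solution pressed against an active bound counts as
   optimal;
5. step tolerance $\max_i |x_{i,j} - x_{i+1,j}| < 5\times10^{-4}$.

Scalar tolerances written against vectors are interpreted in the infinity
norm. Failed forward evaluations (invalid parameters, solver failure)
return a penalty of $10^6(1 + \varphi_{best})$ so the search continues
around pathological regions instead of aborting. `multistart_calibrate()`
runs the loop independently from three standard starting points and keeps
the lowest-objective minimum; `rank_minima()` orders all local minima by
the mean of the three block errors.

## The synthetic study

`make_experiment()` generates ventilation records with known ground
truth. Its defaults are the package's study conditions, fixed once:

* geometry: total volume 2430 mL by submersion, 818 g of tissue at
  1.0 g/cm³, hence 1612 mL of initial air and 66 % porosity;
* ramp: smoothstep $p_{max}(3s^2-2s^3)$ to 2.1 kPa over 2 s (the
  waveform of a piston-driven ventilation system is not tabulated; the
  smoothstep has the right zero-slope endpoints, and a linear ramp is
  available);
* ground truth $\theta^\ast$: $\mu = 2.8$ kPa, $\alpha = 9$,
  $\nu = 0.3$, $k = (2, 1.5, 1.2, 5, 1.5)$ with the middle-right lobe
  the most permeable, $C_{10} = 1$ kPa, $\lambda_{pl} = 0.5$;
* noise: Gaussian and independent per component, 2 % relative on
  volumes, 0.005 absolute on strain statistics (experimental noise
  floors for this kind of rig are unpublished; these are
  order-of-magnitude choices, configurable).

The ground-truth choice deserves its rationale. The parenchymal modulus
is the calibrated human value scale (2.8 kPa); the permeability ordering
follows the finding that the middle-right lobe fills fastest. The
exponent pair $(\alpha, \nu)$ is chosen so that the recoil
$\sigma_{foam}$ first softens (the volumetric term dies off) and then
stiffens steeply — that interplay is what gives the generated PV curve
its lower and upper inflection points *within* the 2.1-kPa ramp, and it
places an inflation equilibrium at a stretch of about 1.22, i.e. lobe
strains of order 0.05–0.25 across the three stages and roughly two liters
of added volume. Parameter sets whose recoil peaks below the ramp
pressure (very small $\alpha$ with a near-inextensible membrane turned
off) have no equilibrium in this compartment geometry — the confinement
that would tame them in a full-organ model (contact, closed pleural sac)
is exactly what the reduced order omits — so such sets are not usable as
generator defaults here, however plausible they are as full-model
calibration outputs. All default ground-truth values are interior to the
calibration bounds.

`make_biaxial()` emulates a 9-donor × 12-sample membrane testing
campaign (108 curves): donor-level lognormal stiffness multipliers
($\sigma = 0.5$) on the shared baseline produce the wide spread such
campaigns show, and per-point Gaussian stress noise (0.5 kPa) the
measurement scatter.

## Numerical choices that matter

* **Integration tolerances vs identifiability.** The airway surrogate
  and the pleura multiplier act on the recoil at the percent level; their
  forward-difference Jacobian columns are small. At the default
  rtol $10^{-8}$ used inside calibration these columns are clean; the
  noiseless *recovery study* tightens to rtol $10^{-10}$ and
  atol $10^{-12}$ so that the weakest column ($\lambda_{pl}$, whose step
  is $3\times10^{-6}$ on a bound width of 3) stays well above the
  integration error. With noisy Jacobians the loop stalls in a flat
  valley; with clean ones the same start converges to machine-level
  $\varphi$ in about ten iterations.
* **Tolerances of the recovery study.** A noiseless record supports
  $\varphi \to 0$, far below the default function tolerance, so the
  recovery tests tighten the function/optimality/step tolerances; the
  default protocol thresholds are kept everywhere data are noisy (the
  reproduction script additionally bounds the noisy fit's iteration
  budget, since its purpose is the noise-floor ratio, not full
  convergence).
* **Stage location.** Stage times are found by linear interpolation of
  the monotone pressure history; the 100 % stage is the ramp endpoint
  exactly.
* **Degenerate inputs.** Zero block normalisers (an experiment with no
  spread in a block) are rejected as degenerate rather than silently
  producing infinite residuals; $\nu = 0.5$ is rejected at construction
  ($\beta$ diverges); zero permeability is admissible and freezes the
  corresponding compartments.
* **Problem sizes.** The shipped tests run the forward model mostly at
  2–5 patches per lobe and 60 output steps on a 600-mL geometry, and the
  recovery study at the standard 20 patches per lobe and 100 steps on
  the full geometry — sizes chosen so the whole suite exercises the real
  pipeline in minutes on a single core.

## Known limitations

The compartment model cannot reproduce location-specific strain contours,
only lobe-level statistics; the within-lobe spread is generated by the
permeability-multiplier mechanism rather than by geometry, so calibrated
heterogeneity constants should not be over-interpreted; permeabilities
are constant (no void-ratio dependence); and the identifiability of the
airway and pleura parameters rests on percent-level signals — with
realistic measurement noise those two parameters are determined only
weakly, which mirrors the flat directions reported for full-scale
inverse analyses of this kind. The interpretation of the flux law's units
is a modelling convention (documented above), not a measured quantity.
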