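---
title: "Multiphase tumor-growth models with entropy-production auditing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase tumor-growth models with entropy-production auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcatsim)
```

## The models

`tcatsim` implements two closed macroscale models of avascular tumor
growth derived in the thermodynamically constrained averaging theory
(TCAT) tradition of porous-medium mechanics: microscale conservation and
thermodynamic equations are averaged to the macroscale, and every
constitutive (closure) relation is chosen so that its contribution to the
system's entropy production is a nonnegative flux–force product. The
package's distinguishing feature is that this property is not an offline
derivation: an *entropy auditor* evaluates every term group of the
restricted entropy inequality numerically, for any state and any
trajectory, and the test suite requires every group to be nonnegative.

**Two-phase model.** A tissue solid `s` (extra-cellular matrix, living
tumor cells `l`, necrotic cells `n`, nutrients, drug, water, background)
is bathed in interstitial fluid `f` (water, glucose `g`, oxygen `o`,
drug `c`, background `x`). Each phase carries volume fraction
$\varepsilon^\alpha$, intrinsic density $\rho^\alpha$, mass fractions
$\omega^{i\alpha}$ and pressure $p^\alpha$, with
$\sum_\alpha \varepsilon^\alpha = 1$ and
$\sum_i \omega^{i\alpha} = 1$. The model solves species mass balances on
a 1-D Cartesian or spherically symmetric finite-volume grid, with:

* **ideal-solution chemical potentials**
  $\mu^{i\alpha} = \mu_0^{i\alpha} + \frac{R_g\theta}{MW_i}\ln x^{i\alpha}$
  (unit activity coefficients, single temperature $\theta$);
* **chemical-potential-driven diffusion**: the deviation mass flux of
  each non-reference species is
  $-\varepsilon\rho\,\hat D_i\nabla(\mu^{i} - \mu^{N})$, where $N$ is the
  dominant reference species (water in fluids, matrix in the solid); the
  reference-species flux closes the constraint
  $\sum_i \omega^i u^i = 0$ exactly;
* **affinity kinetics**: each reaction runs at $R = -\hat K A$ with
  affinity $A = \sum_i \mu^{i}\nu_i MW_i$, so its entropy production
  $\varepsilon\hat K A^2/\theta$ is nonnegative for any state;
* **potential-driven interphase transfer**
  $M^{i} = \hat K_M(\mu^{if}+\psi^f-\mu^{is}-\psi^s)$, likewise
  quadratic in its driving force;
* **quasi-static momentum**: a Darcy-type resistance closure
  $\varepsilon\nabla p - \varepsilon\rho g + \hat R(v_f - v_s) + \ldots = 0$,
  solved together with the overall fluid mass balance as an elliptic
  pressure problem each step.

**Three-phase model.** Tumor cells are treated as a non-wetting fluid
`n` inside a wetting interstitial fluid `w` and a solid scaffold `s`.
The package integrates the well-mixed (0-D) reduction of this model:
compositions and volume fractions evolve by the same kinetic and
transfer closures (all reactions in the tumor-cell phase), while the
geometric state evolves by averaging-theorem evolution equations: the
specific fluid–fluid interfacial area $\varepsilon^{wn}$ relaxes toward
an equilibrium value and responds to volume-fraction changes through the
interface curvature; the Gaussian curvature satisfies
$d(\varepsilon^{wn}K)/dt = 0$ (fixed topology); and the capillary
pressure is obtained each step by inverting the capillary-relaxation
closure at the mass-balance-determined rates, so Young–Laplace
equilibrium ($p^w - p^n = \gamma^{wn}J_w^{wn}$) is the exact fixed
point.

## The entropy auditor

`audit_two_phase()` and `audit_three_phase()` evaluate the
closure-substituted quadratic form of every flux–force group: diffusion
($\varepsilon\rho\,\nabla\Delta\mu\cdot\hat D\cdot\nabla\Delta\mu/\theta$),
reaction ($\varepsilon\hat K A^2/\theta$), transfer
($\hat K_M\Delta^2/\theta$ per phase pair), momentum resistance,
capillary relaxation ($\hat c^{wn}\delta^2/\theta$ with $\delta$ the
Young–Laplace disequilibrium), and porosity change
($\hat c\,[\text{normal-force bracket}]^2/\theta$). Stress groups are
eliminated by zero-order closures and reported as structural zeros so
that the ledger stays aligned with the inequality's term structure. The
audit works on macroscale quantities only — it certifies that the
*closures in use* cannot produce negative entropy, which is exactly the
consistency the inequality is designed to guarantee; it does not (and
cannot) evaluate microscale deviation terms.

Two reporting choices deserve note. The porosity work on the wetted and
non-wetted solid surfaces is only sign-definite in the sum of its two
lines; the ledger apportions the nonnegative total by wetted fraction
$\chi_s^{ws}$ so that every reported group is individually a nonnegative
quadratic form. And with viscous cross-coupling between the fluid
momenta enabled, only the block quadratic form is guaranteed
nonnegative; the shipped default is diagonal resistance, for which the
per-phase groups are individually sign-definite.

## Choices where the formulation is open

* **Reference-state potentials** $\mu_0(p,\theta)$: per-(species, phase)
  constants from the configuration (isothermal, liquid-like
  incompressible phases). The shipped values form a ladder that makes
  the biologically forward direction of every channel spontaneous:
  tumor cells sit far below free glucose + oxygen, necrotic below
  living, lysis products below necrotic. A linear-in-pressure extension
  would be straightforward but is deliberately not a default.
* **Mobility parameterization**: the diffusion tensor is
  $\hat D_i = d_i\,\omega_i MW_i/(R_g\theta)\,\mathbf I$, chosen so a
  dilute solute obeys Fick's law with coefficient $d_i$ — this is the
  standard Maxwell–Stefan-to-Fick degeneration and enables analytic
  verification against the heat kernel.
* **Mole-fraction floor**: potentials use $\ln(x + x_\mathrm{floor})$
  with $x_\mathrm{floor} \le 10^{-6}$ (default $10^{-12}$). The additive
  (rather than hard-clipped) floor keeps the potential finite *and
  smooth* through $x \to 0$, which matters for implicit integrators.
* **Reactant-availability limiters**: the linear affinity closure does
  not itself vanish when a reactant is exhausted — a floored potential is
  finite, so the rate would keep consuming an absent species. Every
  shipped reaction therefore carries a saturable, Monod-like modulation
  $\prod_r \omega_r/(\omega_r + s_r)$ over its reactants. Any
  nonnegative state-dependent factor multiplying $\hat K$ preserves the
  entropy sign, and the saturable form mirrors how the underlying
  biochemical literature parameterizes nutrient dependence.
* **Oxygen gate on necrosis**: the necrotic-formation schema contains no
  oxygen, while the narrative ties necrosis to oxygen starvation. The
  channel's coefficient is modulated by a smooth logistic switch
  $\sigma((\omega_\mathrm{crit} - \omega^o)/\delta)$ with
  $\omega_\mathrm{crit} = 10^{-5}$, $\delta = 2\times10^{-6}$; with the
  gate disabled the channel is off entirely.
* **Porosity**: the solid volume fraction is evolved from the solid
  overall mass balance (transfer divided by the solid density); the
  porosity closure driven by normal surface forces is evaluated as a
  diagnostic only, because the two equations over-determine
  $\varepsilon^s$ when the solid velocity and density are prescribed and
  the formulation does not reconcile them.
* **Solid mechanics**: the solid velocity is zero by default; the total
  momentum equation and finite-strain solid constitutive modeling are
  out of scope. The solid stress enters only through the user-supplied
  effective normal stress in the porosity bracket.
* **Capillary flux refinement**: the capillary-relaxation line of the
  three-phase inequality carries an additional area-relaxation term in
  its flux; we keep area relaxation in the interfacial-area evolution
  equation only, which keeps the capillary-pressure inversion linear and
  exact. The entropy sign is unaffected.
* **Three-phase reaction products**: the tumor-cell phase's member set
  excludes the matrix species, so destruction and lysis in the
  three-phase fixture report their non-aqueous products to the
  tumor-phase background species (dissolved debris) with mass-balanced
  stoichiometry. The reaction set is explicitly an example; alternative
  sets are configuration-level choices.
* **0-D geometry**: the average interface normal is zero (isotropic
  case); orientation tensors are constant $\mathbf I/3$; the mean
  curvature follows $J \propto \sqrt{K}$ (spherical self-similarity);
  the equilibrium interfacial area is a user-supplied function of
  wetting saturation, defaulting to a quadratic bump; topological events
  (vanishing interfaces) are run-terminating errors. The solid-contact
  area $\varepsilon^{ns}$ and solid curvature are configuration
  constants, as the formulation provides no evolution equations for
  them.

## Numerical scheme

Cell-centered finite volumes with two-point fluxes for diffusion and the
Darcy term, first-order upwinding for advection, exact spherical shell
volumes, and half-open cells. Each right-hand-side evaluation performs
the sequential (IMPES-like) split: kinetics and transfer from current
potentials, tridiagonal elliptic pressure solve (Dirichlet at the outer
boundary by default, symmetry at the origin for spherical runs,
gauge-cell pinning for all-Neumann problems), Darcy velocity, then
transport. Time integration is method-of-lines with implicit stiff
integrators from `deSolve` (`vode`/`lsoda`/`lsodes`, configurable
`rtol`/`atol`). The splitting is first order in time; the prognostic set
is $\{\varepsilon^s\}$ plus the non-reference mass fractions, with the
reference species and $\varepsilon^f = 1 - \varepsilon^s$ closed
algebraically so the sum constraints hold exactly at all times.

The pressure equation makes the divergence of the Darcy flux consistent
with the interphase volume source $T(1/\rho_s - 1/\rho_f)$, so closed
domains conserve total mass to integrator precision. In the well-mixed
three-phase box there is no pressure field to absorb volume changes, so
the shipped three-phase scenarios use a single tissue-like density
(1000 kg/m³) for all phases, under which $\sum_\alpha\varepsilon^\alpha = 1$
is preserved exactly under transfer.

## The synthetic scenarios and what they emulate

The *avascular spheroid* scenario (`build_spheroid_fixture()`) is a
5 mm spherical domain, 16 radial cells by default, solid fraction 0.3,
with glucose and oxygen held at the outer boundary, physical solute
diffusivities ($2\times10^{-9}$ m²/s oxygen, $7\times10^{-10}$ m²/s
glucose), and the four-channel reaction network. Rate coefficients were
set by a supply–demand scale analysis: oxygen consumption by tumor
formation is balanced against transmural transfer and radial diffusion
so that the core oxygen settles near the necrosis switch scale
($10^{-5}$ mass fraction) rather than collapsing to zero — the
avascular-spheroid regime of interest. Under an oxygen-rich boundary
($3\times10^{-4}$) the living-tumor mass grows monotonically at the
percent level over the default $10^4$ s horizon; under the standard
boundary ($5\times10^{-5}$) the core turns hypoxic and necrosis
accumulates; enabling the drug pathway (boundary drug, fluid–solid drug
transfer and the destruction channel) strictly reduces the final tumor
burden relative to the drug-free control at the same seed.

What these scenarios do *not* emulate: vasculature and angiogenesis,
poroelastic deformation (the solid is rigid and immobile), 2-D/3-D
geometry, temperature fields, and non-ideal activity. Passing tests
certify internal consistency (conservation, thermodynamic
admissibility, convergence to analytic limits, recoverability of
parameters) — they do not certify biological calibration against real
spheroid data.

The problem sizes used by the shipped verification runs (16–256 cells,
$10^4$ s horizons, 100-state audit ensembles, 20 noisy recovery
replicates) were chosen so the whole battery reruns comfortably on a
single CPU while leaving each check's discriminating power intact; all
are parameters, not constants, and scale up directly.

## Verification strategy

* **Analytic oracles**: the dilute-solute run against the Gaussian heat
  kernel (L2 error 0.14% at 128 cells, observed convergence order
  ≈ 1.9); the two-point Dirichlet pressure problem against the exact
  linear profile (reproduced to round-off); hydrostatic quiescence; the
  scalar exponential for interfacial-area relaxation; the sphere-pack
  family for the Gauss–Bonnet identity and the integral-geometry state
  function (recovered exactly in log space).
* **Independent numerical oracles**: the one-cell transfer scenario
  against a separately coded three-variable compartment ODE; the
  semi-discrete diffusion operator against an independently assembled
  two-point-flux matrix; the Galilean-invariance residual against
  hand-differentiated trigonometric fields under grid refinement.
* **Structural invariants**: per-reaction mass conservation at machine
  precision, transfer antisymmetry, closure of the sum constraints,
  conservation of $\varepsilon^{wn}K$, capillary inversion round trips,
  and the nonnegativity of every entropy-ledger group for seeded random
  states and along every shipped trajectory.
* **Inverse problems**: transfer and reaction coefficients re-estimated
  from synthetic trajectories by trajectory-matching least squares
  (golden-section search on $\log_{10}K$), exact to ~$10^{-4}$%
  noiseless and within a few percent under 1% multiplicative noise.

## Known limitations

The affinity closure is linear in the affinity; saturable kinetics enter
only through the nonnegative modulation factors. Stiffness grows sharply
when any participating species approaches zero (logarithmic potential
slopes); the limiters bound this but very stiff parameter regimes may
still need tighter tolerances or shorter steps. The three-phase model is
well-mixed only — no spatial three-phase solver is provided. Common-curve
dynamics, interface inertia, and wetted-fraction evolution are omitted
(the wetted fraction is constant). The conservation report integrates
recorded rates with the trapezoid rule over output times, so its
reaction/transfer balances are output-resolution-limited.
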