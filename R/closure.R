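## Algebraic constitutive closures permitted by the restricted simplified
## entropy inequalities: stress, chemical-potential-driven diffusion,
## momentum resistance, porosity evolution, capillary relaxation.

#' Closure coefficients
#'
#' Container for the constitutive coefficients appearing in the
#' entropy-inequality-consistent closures.  Tensors may be given as scalars
#' (isotropic), length-3 diagonals, or full 3x3 symmetric matrices.
#'
#' @param diffusivity named list per phase of named numeric vectors of
#'   species mobility diffusivities `d_i` (m^2/s).
#' @param resistance named list per fluid phase of resistance tensors `R`
#'   (positive semidefinite); optional `cross` entries couple fluid pairs.
#' @param compressibility nonnegative solid compressibility `c_hat`
#'   (porosity closure), Pa^-1 s^-1 scale.
#' @param tension named numeric vector of interfacial tensions (N/m), e.g.
#'   `c(fs = ..., wn = ..., ws = ..., ns = ...)`.
#' @param orientation named list of interface orientation tensors `G`
#'   (trace 1; default isotropic `I/3`).
#' @param area_relaxation nonnegative interfacial-area relaxation rate
#'   `k_wn` (1/s).
#' @param capillary_relaxation nonnegative capillary-pressure relaxation
#'   coefficient `c_wn`.
#' @param contact_angle constant contact angle through the wetting phase
#'   (radians).
#' @return object of class `closure_coeffs`.
#' @export
closure_coeffs <- function(diffusivity = list(), resistance = list(),
                           compressibility = 0, tension = numeric(0),
                           orientation = list(), area_relaxation = 0,
                           capillary_relaxation = 0, contact_angle = 0) {
  for (ph in names(diffusivity))
    if (any(unlist(diffusivity[[ph]]) < 0))
      stop("diffusivities must be nonnegative (phase '", ph, "')")
  if (compressibility < 0) stop("compressibility must be nonnegative")
  if (any(tension < 0)) stop("interfacial tensions must be nonnegative")
  if (area_relaxation < 0) stop("area_relaxation must be nonnegative")
  if (capillary_relaxation < 0)
    stop("capillary_relaxation must be nonnegative")
  structure(list(diffusivity = diffusivity, resistance = resistance,
                 compressibility = compressibility, tension = tension,
                 orientation = orientation,
                 area_relaxation = area_relaxation,
                 capillary_relaxation = capillary_relaxation,
                 contact_angle = contact_angle),
            class = "closure_coeffs")
}

## Expand a scalar / diagonal / matrix coefficient into a 3x3 matrix.
as_tensor <- function(x, name = "tensor") {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(3, 3))) stop(name, " must be 3x3")
    if (max(abs(x - t(x))) > 1e-12 * max(1, max(abs(x))))
      stop(name, " must be symmetric")
    x
  } else if (length(x) == 1) {
    diag(3) * x
  } else if (length(x) == 3) {
    diag(as.numeric(x))
  } else stop(name, " must be a scalar, length-3 diagonal, or 3x3 matrix")
}

#' Zero-order fluid/solid phase stress closure
#'
#' `t = -p I`: fluid flow through the medium is treated as inviscid at the
#' macroscale, momentum exchange with the solid being the dominant
#' dissipation channel.
#'
#' @param pressure phase pressure in Pa.
#' @return 3x3 stress tensor in Pa.
#' @export
phase_stress <- function(pressure) {
  -pressure * diag(3)
}

#' Interfacial stress closure
#'
#' `t = gamma * (I - G)` with the orientation tensor `G` of trace 1; the
#' trace of the result is `2 * gamma`.
#'
#' @param tension interfacial tension gamma (N/m).
#' @param orientation orientation tensor `G` (scalar/diagonal/matrix);
#'   default isotropic `I/3`.
#' @return 3x3 interface stress tensor (N/m).
#' @export
interface_stress <- function(tension, orientation = rep(1 / 3, 3)) {
  G <- as_tensor(orientation, "orientation")
  if (abs(sum(diag(G)) - 1) > 1e-10)
    stop("orientation tensor must have trace 1")
  tension * (diag(3) - G)
}

## Mobility tensor of the chemical-potential diffusion closure:
## D_i = d_i * omega_i * MW_i / (R_g theta) so that the dilute limit
## degenerates to Fickian diffusion with coefficient d_i.
mobility <- function(d_i, omega_i, mw_i, thermo) {
  d_i * omega_i * mw_i / (thermo$gas_constant * thermo$temperature)
}

#' Diffusive (deviation-velocity) mass fluxes within a phase
#'
#' First-order closure: the mass flux of each non-reference species is
#' `eps * rho * omega_i * u_i = -eps * rho * D_i * grad(mu_i - mu_N)`,
#' where `N` is the phase reference species and
#' `D_i = d_i omega_i MW_i / (R_g theta)` (so a dilute solute diffuses
#' Fickianly with coefficient `d_i`).  The reference-species flux is the
#' negative sum of the others, enforcing `sum_i omega_i u_i = 0` exactly.
#'
#' @param phase a [phase_def()].
#' @param eps phase volume fraction.
#' @param rho phase density (kg/m^3).
#' @param omega named mass-fraction vector for the phase members.
#' @param potential_gradients named numeric vector (1-D gradients of
#'   `mu_i`, J/(kg m)) for the phase members.
#' @param coeffs a [closure_coeffs()].
#' @param thermo a [thermo_params()].
#' @param species a [species_table()].
#' @return named vector of species mass fluxes in kg/(m^2 s).
#' @export
diffusive_flux <- function(phase, eps, rho, omega, potential_gradients,
                           coeffs, thermo, species) {
  bad <- setdiff(names(potential_gradients), phase$members)
  if (length(bad))
    stop("potential gradient supplied for non-member species: ",
         paste(bad, collapse = ", "))
  ref <- phase$reference_species
  others <- setdiff(phase$members, ref)
  dvec <- coeffs$diffusivity[[phase$phase_id]]
  flux <- stats::setNames(numeric(length(phase$members)), phase$members)
  gref <- if (ref %in% names(potential_gradients))
    potential_gradients[[ref]] else 0
  for (sp in others) {
    g <- if (sp %in% names(potential_gradients))
      potential_gradients[[sp]] else 0
    d_i <- if (!is.null(dvec) && sp %in% names(dvec)) dvec[[sp]] else 0
    D <- mobility(d_i, omega[[sp]], species$molar_mass[[sp]], thermo)
    flux[[sp]] <- -eps * rho * D * (g - gref)
  }
  flux[[ref]] <- -sum(flux[others])
  flux
}

#' Quasi-static fluid velocity from the closed momentum balance
#'
#' Solves `eps * grad p - eps * rho * g + R (v_f - v_s) +
#' sum_i M_i (v_f + u_i) = 0` for `v_f`.  Without transfer the closed form
#' is `v_f = v_s - R^{-1} eps (grad p - rho g)`; with transfer the equation
#' is solved by Picard iteration lagging `v_f` (tolerance 1e-12, at most 50
#' iterations).
#'
#' @param eps fluid volume fraction.
#' @param rho fluid density (kg/m^3).
#' @param pressure_gradient length-3 pressure gradient (Pa/m); scalars are
#'   taken as the x component.
#' @param gravity length-3 body acceleration (m/s^2).
#' @param resistance resistance tensor `R` (scalar/diagonal/matrix).
#' @param v_s solid velocity (default 0).
#' @param transfer_rates optional named numeric vector of species transfer
#'   rates `M_i` (kg/(m^3 s), fluid to solid positive).
#' @param deviation_velocities optional named list of species deviation
#'   velocities `u_i` (length-3 each).
#' @return length-3 fluid velocity (m/s).
#' @export
fluid_velocity <- function(eps, rho, pressure_gradient, gravity = c(0, 0, 0),
                           resistance = 1, v_s = c(0, 0, 0),
                           transfer_rates = NULL,
                           deviation_velocities = NULL) {
  vec3 <- function(x) if (length(x) == 1) c(x, 0, 0) else as.numeric(x)
  gp <- vec3(pressure_gradient); g <- vec3(gravity); vs <- vec3(v_s)
  R <- as_tensor(resistance, "resistance")
  force0 <- eps * gp - eps * rho * g
  no_transfer <- is.null(transfer_rates) || all(transfer_rates == 0)
  solve_or_fail <- function(A, b) {
    if (abs(det(A)) < 1e-300) {
      if (max(abs(b)) == 0) return(rep(0, 3))
      stop("singular resistance tensor with nonzero driving force")
    }
    solve(A, b)
  }
  if (no_transfer)
    return(vs - solve_or_fail(R, force0))
  Mtot <- sum(transfer_rates)
  udev <- function(sp) {
    if (is.null(deviation_velocities) ||
        !sp %in% names(deviation_velocities)) rep(0, 3)
    else vec3(deviation_velocities[[sp]])
  }
  v <- vs - solve_or_fail(R, force0)   # transfer-free initial iterate
  for (it in seq_len(50)) {
    extra <- Mtot * v
    for (sp in names(transfer_rates))
      extra <- extra + transfer_rates[[sp]] * udev(sp)
    v_new <- vs - solve_or_fail(R, force0 + extra)
    if (max(abs(v_new - v)) <= 1e-12 * max(1, max(abs(v_new)))) return(v_new)
    v <- v_new
  }
  stop("fluid_velocity: Picard iteration did not converge in 50 iterations")
}

#' Porosity evolution rate from normal solid-surface forces
#'
#' Two-phase closure `D eps / Dt = c_hat * [p + (n.t.n) + gamma * J]`, where
#' the bracket collects the fluid pressure at the fluid-solid interface, the
#' effective solid normal stress and the curvature-tension term.  The
#' three-phase analogue weights the fluid terms by wetted fraction.
#'
#' @param bracket the normal-force bracket (Pa): either supplied directly,
#'   or computed via [porosity_bracket()].
#' @param compressibility nonnegative coefficient `c_hat`.
#' @return porosity rate in 1/s.
#' @export
porosity_rate <- function(bracket, compressibility) {
  if (compressibility < 0) stop("compressibility must be nonnegative")
  compressibility * bracket
}

#' Normal-force bracket for the porosity closure
#'
#' Two-phase: `p_f + sigma_n + gamma_fs * J_s`.  Three-phase
#' (wetted-fraction weighted):
#' `chi_ws p_w + chi_ns p_n + sigma_n + (chi_ws gamma_ws + chi_ns gamma_ns) J_s`.
#'
#' @param p_fluid fluid pressure(s) at the solid surface: a single value
#'   (two-phase) or `c(w = ..., n = ...)` (three-phase).
#' @param solid_normal_stress effective solid normal stress `(n.t.n)` (Pa).
#' @param tension interfacial tension(s): single value or
#'   `c(ws = ..., ns = ...)`.
#' @param curvature solid-surface mean curvature `J_s` (1/m).
#' @param wetted_fraction `chi_ws` in \[0,1\] (three-phase); `NULL` for
#'   two-phase.
#' @return bracket value in Pa.
#' @export
porosity_bracket <- function(p_fluid, solid_normal_stress, tension,
                             curvature, wetted_fraction = NULL) {
  if (is.null(wetted_fraction)) {
    p_fluid + solid_normal_stress + tension * curvature
  } else {
    chi_w <- wetted_fraction; chi_n <- 1 - wetted_fraction
    chi_w * p_fluid[["w"]] + chi_n * p_fluid[["n"]] + solid_normal_stress +
      (chi_w * tension[["ws"]] + chi_n * tension[["ns"]]) * curvature
  }
}

#' Capillary-pressure relaxation rate
#'
#' First-order relaxation of capillary pressure toward Young-Laplace
#' equilibrium: rate `= c_wn * (p_w - p_n - gamma_wn * J_w)`, zero exactly
#' when `p_w - p_n = gamma * J`.
#'
#' @param p_w wetting-fluid pressure at the fluid-fluid interface (Pa).
#' @param p_n non-wetting-fluid pressure at the interface (Pa).
#' @param tension fluid-fluid interfacial tension `gamma_wn` (N/m).
#' @param curvature interface mean curvature `J_w` (1/m).
#' @param coeff nonnegative relaxation coefficient `c_wn`.
#' @return relaxation rate in 1/s.
#' @export
capillary_relaxation_rate <- function(p_w, p_n, tension, curvature, coeff) {
  if (coeff < 0) stop("capillary relaxation coefficient must be nonnegative")
  coeff * (p_w - p_n - tension * curvature)
}

#' Invert the capillary-relaxation closure for the capillary pressure
#'
#' Given the kinematic left-hand side `rate` of the relaxation closure,
#' returns the capillary pressure `p_w - p_n = gamma * J + rate / c_wn`.
#' Re-evaluating [capillary_relaxation_rate()] at the result reproduces
#' `rate` exactly.
#'
#' @param rate kinematic rate (1/s).
#' @param tension `gamma_wn` (N/m).
#' @param curvature `J_w` (1/m).
#' @param coeff positive coefficient `c_wn`.
#' @return capillary pressure `p_w - p_n` in Pa.
#' @export
invert_capillary_pressure <- function(rate, tension, curvature, coeff) {
  if (coeff <= 0) stop("inversion requires a positive relaxation coefficient")
  tension * curvature + rate / coeff
}
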