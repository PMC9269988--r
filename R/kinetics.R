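## Affinity-based homogeneous reactions and conjugate flux-force
## interphase mass transfer.

#' Reaction specification
#'
#' A homogeneous reaction in one phase with signed molar stoichiometric
#' coefficients (reactants negative, products positive) and a nonnegative
#' affinity-rate coefficient `K`.  With the linear closure `R = -K * A` the
#' forward direction is spontaneous when the products carry lower total
#' chemical potential, and the entropy production `eps * K * A^2 / theta` is
#' nonnegative for any state.
#'
#' An optional `modulation` function of the phase mass-fraction vector may
#' scale `K` by a nonnegative, state-dependent factor (used for the
#' oxygen-starvation switch on necrotic formation); any nonnegative factor
#' preserves the entropy-inequality sign.
#'
#' @param id reaction identifier.
#' @param phase phase symbol in which the reaction occurs.
#' @param stoich named numeric vector of signed molar coefficients `nu`.
#' @param rate_coeff nonnegative rate coefficient `K` (mol^2 K / (J m^3 s)).
#' @param modulation optional function `(omega) -> factor >= 0`.
#' @return object of class `reaction_spec`.
#' @export
reaction_spec <- function(id, phase, stoich, rate_coeff, modulation = NULL) {
  if (length(stoich) == 0 || is.null(names(stoich)))
    stop("stoich must be a non-empty named vector")
  if (!is.numeric(rate_coeff) || rate_coeff < 0)
    stop("rate_coeff must be nonnegative")
  if (!is.null(modulation) && !is.function(modulation))
    stop("modulation must be a function or NULL")
  structure(list(id = id, phase = phase, stoich = stoich,
                 rate_coeff = rate_coeff, modulation = modulation),
            class = "reaction_spec")
}

#' Balance a stoichiometry by solving for one free coefficient
#'
#' Reaction schemata fix all but one molar coefficient; the free one is
#' solved from the mass-balance requirement `sum_i nu_i MW_i = 0`.
#'
#' @param stoich named numeric vector with the free species set to `NA`.
#' @param free_species symbol of the species whose coefficient is solved.
#' @param species a [species_table()].
#' @return the completed stoichiometry vector.
#' @export
balance_stoichiometry <- function(stoich, free_species, species) {
  if (!free_species %in% names(stoich))
    stop("free_species not in stoichiometry")
  mw <- species$molar_mass[names(stoich)]
  if (anyNA(mw)) stop("unknown species in stoichiometry")
  others <- setdiff(names(stoich), free_species)
  stoich[free_species] <- -sum(stoich[others] * mw[others]) / mw[[free_species]]
  stoich
}

#' Validate a reaction against the species table
#'
#' Checks the mass balance `sum_i nu_i MW_i = 0` (within `tol`) and the sign
#' of the rate coefficient.
#'
#' @param reaction a [reaction_spec()].
#' @param species a [species_table()].
#' @param tol mass-balance tolerance in kg/mol.
#' @return list with `ok` (logical), `residual` (kg/mol) and `message`.
#' @export
validate_reaction <- function(reaction, species, tol = 1e-12) {
  mw <- species$molar_mass[names(reaction$stoich)]
  if (anyNA(mw))
    return(list(ok = FALSE, residual = NA_real_,
                message = paste("unknown species:",
                                paste(names(reaction$stoich)[is.na(mw)],
                                      collapse = ", "))))
  residual <- sum(reaction$stoich * mw)
  ok <- abs(residual) <= tol && reaction$rate_coeff >= 0
  msg <- if (abs(residual) > tol)
    sprintf("reaction '%s' unbalanced: residual mass %.6g kg/mol",
            reaction$id, residual)
  else if (reaction$rate_coeff < 0)
    sprintf("reaction '%s' has negative rate coefficient", reaction$id)
  else "ok"
  list(ok = ok, residual = residual, message = msg)
}

#' Chemical affinity of a reaction
#'
#' `A = sum_i mu_i nu_i MW_i` (J/mol).  Zero at chemical equilibrium; for a
#' mass-balanced stoichiometry it is invariant under a uniform additive shift
#' of all potentials.
#'
#' @param reaction a [reaction_spec()].
#' @param potentials named numeric vector of chemical potentials (J/kg) for
#'   at least every species in the stoichiometry.
#' @param species a [species_table()].
#' @return affinity in J/mol.
#' @export
affinity <- function(reaction, potentials, species) {
  need <- names(reaction$stoich)
  if (!all(need %in% names(potentials)))
    stop("missing chemical potential for: ",
         paste(setdiff(need, names(potentials)), collapse = ", "))
  mw <- species$molar_mass[need]
  sum(potentials[need] * reaction$stoich * mw)
}

#' Linear affinity-closure reaction rate
#'
#' `R = -K * A` with `K >= 0` (after optional modulation).  The conjugate
#' entropy production `eps * K * A^2 / theta` is nonnegative identically.
#'
#' @param reaction a [reaction_spec()].
#' @param affinity affinity in J/mol.
#' @param omega optional phase mass-fraction vector passed to the modulation
#'   factor.
#' @return molar rate in mol/(m^3 s).
#' @export
reaction_rate <- function(reaction, affinity, omega = NULL) {
  k <- effective_rate_coeff(reaction, omega)
  -k * affinity
}

effective_rate_coeff <- function(reaction, omega = NULL) {
  k <- reaction$rate_coeff
  if (k < 0) stop("negative rate coefficient")
  if (!is.null(reaction$modulation)) {
    f <- reaction$modulation(omega)
    if (any(!is.finite(f)) || any(f < 0))
      stop("modulation factor must be finite and nonnegative")
    k <- k * f
  }
  k
}

#' Oxygen-starvation switch
#'
#' Smooth logistic modulation factor `sigma((omega_crit - omega_o) / delta)`
#' for the necrotic-formation channel: close to 1 when local oxygen falls
#' below `omega_crit`, close to 0 when oxygen is abundant.
#'
#' @param omega_crit critical oxygen mass fraction.
#' @param delta switch width (mass-fraction units).
#' @param oxygen_species symbol of the oxygen species.
#' @return a modulation function suitable for [reaction_spec()].
#' @export
oxygen_switch <- function(omega_crit = 1e-5, delta = 2e-6,
                          oxygen_species = "o") {
  force(omega_crit); force(delta); force(oxygen_species)
  function(omega) {
    wo <- get_omega_col(omega, oxygen_species)
    stats::plogis((omega_crit - wo) / delta)
  }
}

## Column/element lookup working for named vectors and matrices with named
## columns (vectorized over cells).
get_omega_col <- function(omega, sp) {
  if (is.null(omega)) return(0)
  if (is.matrix(omega)) {
    if (sp %in% colnames(omega)) omega[, sp] else rep(0, nrow(omega))
  } else {
    if (sp %in% names(omega)) omega[[sp]] else 0
  }
}

#' Reactant-availability limiter
#'
#' Smooth nonnegative modulation factor `prod_i omega_i / (omega_i +
#' scale)` over the listed reactant species: the rate vanishes as any
#' reactant is exhausted (saturable, Monod-like dependence), preventing the
#' linear affinity closure from consuming absent species.  Any nonnegative
#' state-dependent factor preserves the entropy-inequality sign.
#'
#' @param reactant_species character vector of reactant symbols.
#' @param scale half-saturation mass fraction.
#' @return a modulation function suitable for [reaction_spec()].
#' @export
reactant_limiter <- function(reactant_species, scale = 1e-6) {
  force(reactant_species); force(scale)
  function(omega) {
    f <- 1
    for (sp in reactant_species) {
      w <- pmax(get_omega_col(omega, sp), 0)
      f <- f * w / (w + scale)
    }
    f
  }
}

#' Combine modulation factors multiplicatively
#'
#' @param ... modulation functions.
#' @return a modulation function equal to the product of the inputs.
#' @export
compose_modulation <- function(...) {
  fs <- list(...)
  function(omega) {
    out <- fs[[1]](omega)
    for (f in fs[-1]) out <- out * f(omega)
    out
  }
}

#' Species mass production from a reaction network
#'
#' `r_i = sum_k nu_ik MW_i R_k` per phase (kg/(m^3 s)).  Each reaction
#' conserves mass exactly, so the per-reaction contributions sum to zero over
#' species.
#'
#' @param network list of [reaction_spec()] objects.
#' @param potentials named list per phase of named potential vectors (J/kg).
#' @param species a [species_table()].
#' @param omega named list per phase of mass-fraction vectors (for
#'   modulation factors and membership checks); optional.
#' @param phase_defs optional named list of [phase_def()]; when given,
#'   reactions must only involve members of their phase.
#' @return named list per phase of named production-rate vectors.
#' @export
species_production <- function(network, potentials, species, omega = NULL,
                               phase_defs = NULL) {
  out <- list()
  for (rx in network) {
    ph <- rx$phase
    if (!is.null(phase_defs)) {
      pd <- phase_defs[[ph]]
      if (is.null(pd)) stop("reaction '", rx$id, "' assigned to unknown phase '",
                            ph, "'")
      bad <- setdiff(names(rx$stoich), pd$members)
      if (length(bad))
        stop("reaction '", rx$id, "' involves species not in phase '", ph,
             "': ", paste(bad, collapse = ", "))
    }
    mu <- potentials[[ph]]
    if (is.null(mu)) stop("no potentials supplied for phase '", ph, "'")
    A <- affinity(rx, mu, species)
    R <- reaction_rate(rx, A, omega[[ph]])
    mw <- species$molar_mass[names(rx$stoich)]
    contrib <- rx$stoich * mw * R
    if (is.null(out[[ph]])) out[[ph]] <- numeric(0)
    for (sp in names(contrib)) {
      cur <- if (sp %in% names(out[[ph]])) out[[ph]][[sp]] else 0
      out[[ph]][[sp]] <- cur + contrib[[sp]]
    }
  }
  out
}

#' Interphase mass-transfer specification
#'
#' Transfer of one species between two phases, driven by the difference in
#' augmented potentials `mu + psi`, with nonnegative coefficient `K_M`:
#' `M(donor -> receiver) = K_M * (mu_d + psi_d - mu_r - psi_r)`.
#'
#' @param species species symbol; must be a member of both phases.
#' @param donor donor phase symbol.
#' @param receiver receiver phase symbol.
#' @param transfer_coeff nonnegative coefficient `K_M`.
#' @return object of class `transfer_spec`.
#' @export
transfer_spec <- function(species, donor, receiver, transfer_coeff) {
  if (!is.numeric(transfer_coeff) || transfer_coeff < 0)
    stop("transfer_coeff must be nonnegative")
  if (donor == receiver) stop("donor and receiver phases must differ")
  structure(list(species = species, donor = donor, receiver = receiver,
                 transfer_coeff = transfer_coeff),
            class = "transfer_spec")
}

#' Mass-transfer density rate
#'
#' `M = K_M * (mu_donor + psi_donor - mu_receiver - psi_receiver)` in
#' kg/(m^3 s), positive from donor to receiver; antisymmetric under swapping
#' the roles.  The conjugate entropy production `K_M * delta^2 / theta` is
#' nonnegative identically.
#'
#' @param spec a [transfer_spec()].
#' @param potentials named list per phase of named potential vectors (J/kg).
#' @param body_potentials named numeric vector of per-phase body potentials
#'   `psi` (J/kg); missing phases default to 0.
#' @param phase_defs optional named list of [phase_def()] for the shared
#'   -membership check.
#' @return transfer rate in kg/(m^3 s) (donor to receiver).
#' @export
transfer_rate <- function(spec, potentials, body_potentials = NULL,
                          phase_defs = NULL) {
  if (!is.null(phase_defs)) {
    for (ph in c(spec$donor, spec$receiver)) {
      pd <- phase_defs[[ph]]
      if (is.null(pd) || !spec$species %in% pd$members)
        stop("species '", spec$species, "' is not shared by phases '",
             spec$donor, "' and '", spec$receiver, "'")
    }
  }
  psi <- function(ph) {
    if (is.null(body_potentials) || !ph %in% names(body_potentials)) 0
    else body_potentials[[ph]]
  }
  mu_d <- potentials[[spec$donor]][[spec$species]]
  mu_r <- potentials[[spec$receiver]][[spec$species]]
  if (is.null(mu_d) || is.null(mu_r))
    stop("missing potential for species '", spec$species, "'")
  spec$transfer_coeff * (mu_d + psi(spec$donor) - mu_r - psi(spec$receiver))
}
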