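## Species registry, phase membership, and macroscale thermodynamics.

#' Species table
#'
#' Registry of the chemical species resolved by a model, with molar masses.
#' The two-phase tumor model resolves nine species: living tumor cells `l`,
#' necrotic tumor cells `n`, extra-cellular matrix `e`, glucose `g`, oxygen
#' `o`, a chemotherapeutic drug `c`, water `w`, and collective background
#' species `x` (fluid) and `y` (solid).  The three-phase model adds a second
#' background species `z` for the wetting fluid.
#'
#' @param molar_mass named numeric vector of molar masses in kg/mol; names
#'   are the species symbols.
#' @return object of class `species_table` with elements `ids` and
#'   `molar_mass`.
#' @examples
#' st <- species_table(c(w = 0.018, o = 0.032))
#' @export
species_table <- function(molar_mass) {
  if (is.null(names(molar_mass)) || anyDuplicated(names(molar_mass)))
    stop("molar_mass must be a named vector with unique species symbols")
  if (any(!is.finite(molar_mass)) || any(molar_mass <= 0))
    stop("all molar masses must be finite and strictly positive")
  structure(list(ids = names(molar_mass),
                 molar_mass = molar_mass),
            class = "species_table")
}

#' @export
print.species_table <- function(x, ...) {
  cat("<species_table> ", length(x$ids), " species\n", sep = "")
  print(x$molar_mass)
  invisible(x)
}

#' Default species tables for the shipped models
#'
#' Molar masses for water, oxygen and glucose are physical; the cellular and
#' matrix "species" are coarse-grained continuum species and carry
#' illustrative effective molar masses (documented in the methods vignette).
#'
#' @param model `"2p"` (nine species) or `"3p"` (ten species).
#' @return a [species_table()].
#' @export
default_species_table <- function(model = c("2p", "3p")) {
  model <- match.arg(model)
  mw <- c(l = 1.0, n = 1.0, e = 0.5, g = 0.180, o = 0.032,
          c = 0.300, w = 0.018, x = 0.100, y = 0.500)
  if (model == "3p") mw <- c(mw, z = 0.100)
  species_table(mw)
}

#' Phase definition
#'
#' Declares which species a phase may contain and which member is the
#' dominant reference species eliminated through the closure constraint
#' `sum(omega) = 1` (water in fluid phases, the living tumor species in the
#' tumor cell fluid, the extra-cellular matrix species in the solid).
#'
#' @param phase_id phase symbol (`"f"`, `"s"` for two-phase models;
#'   `"w"`, `"n"`, `"s"` for three-phase models).
#' @param members character vector of member species symbols.
#' @param reference_species the dominant species; must be a member.
#' @param species table of known species ([species_table()]).
#' @return object of class `phase_def`.
#' @export
phase_def <- function(phase_id, members, reference_species, species = NULL) {
  if (!is.character(phase_id) || length(phase_id) != 1L)
    stop("phase_id must be a single symbol")
  if (anyDuplicated(members)) stop("phase members must be unique")
  if (!reference_species %in% members)
    stop("reference_species '", reference_species, "' is not a member of phase '",
         phase_id, "'")
  if (!is.null(species) && !all(members %in% species$ids))
    stop("unknown species in phase '", phase_id, "': ",
         paste(setdiff(members, species$ids), collapse = ", "))
  structure(list(phase_id = phase_id, members = members,
                 reference_species = reference_species),
            class = "phase_def")
}

#' Default phase memberships
#'
#' Two-phase: the fluid (interstitial) phase carries `{g,o,c,w,x}` with water
#' as reference; the solid carries `{l,n,e,g,o,c,w,y}` with the matrix
#' species as reference.  Three-phase memberships follow the wetting /
#' non-wetting / solid split of the tumor-cell-as-fluid model.
#'
#' @param model `"2p"` or `"3p"`.
#' @return named list of [phase_def()] objects.
#' @export
default_phase_defs <- function(model = c("2p", "3p")) {
  model <- match.arg(model)
  st <- default_species_table(model)
  if (model == "2p") {
    list(
      f = phase_def("f", c("g", "o", "c", "w", "x"), "w", st),
      s = phase_def("s", c("l", "n", "e", "g", "o", "c", "w", "y"), "e", st)
    )
  } else {
    list(
      w = phase_def("w", c("g", "o", "c", "w", "z"), "w", st),
      n = phase_def("n", c("l", "n", "g", "o", "c", "w", "x"), "l", st),
      s = phase_def("s", c("e", "g", "o", "w", "y"), "e", st)
    )
  }
}

#' Thermodynamic parameters
#'
#' Single-temperature (isothermal) ideal-solution thermodynamics with unit
#' activity coefficients.  `mu0` holds reference-state chemical potentials in
#' J/kg as a named list per phase of named numeric vectors per species; it
#' defaults to zero for every species.
#'
#' @param temperature system temperature in K.
#' @param gas_constant ideal gas constant in J/(mol K).
#' @param mu0 reference-state chemical potentials, `mu0[[phase]][species]`
#'   in J/kg.  Missing entries default to 0.
#' @param x_floor mole-fraction floor applied inside the logarithm only,
#'   in (0, 1e-6].
#' @return object of class `thermo_params`.
#' @export
thermo_params <- function(temperature = 310, gas_constant = 8.314,
                          mu0 = list(), x_floor = 1e-12) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive")
  if (x_floor <= 0 || x_floor > 1e-6)
    stop("x_floor must lie in (0, 1e-6]")
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 mu0 = mu0, x_floor = x_floor),
            class = "thermo_params")
}

mu0_for <- function(thermo, phase_id, species_ids) {
  v <- rep(0, length(species_ids))
  names(v) <- species_ids
  ref <- thermo$mu0[[phase_id]]
  if (!is.null(ref)) {
    hit <- intersect(names(ref), species_ids)
    v[hit] <- ref[hit]
  }
  v
}

## Validate a mass-fraction vector: values in [-1e-12, ...], sum 1 within tol.
## Values in [-1e-12, 0) are zeroed with a warning; below that is an error.
check_mass_fractions <- function(omega, tol = 1e-10) {
  if (any(omega < -1e-12))
    stop("negative mass fraction(s): ",
         paste(names(omega)[omega < -1e-12], collapse = ", "))
  if (any(omega < 0)) {
    warning("mass fractions in [-1e-12, 0) zeroed")
    omega[omega < 0] <- 0
  }
  if (abs(sum(omega) - 1) > tol)
    stop("mass fractions not normalized: sum = ", format(sum(omega), digits = 15))
  omega
}

#' Phase molecular weight
#'
#' Harmonic-mean molar mass of a phase,
#' `MW = 1 / sum_i(omega_i / MW_i)`, equal to the mole-fraction-weighted
#' arithmetic mean `sum_i MW_i x_i`.
#'
#' @param mass_fractions named numeric vector, normalized over the phase
#'   members.
#' @param species a [species_table()].
#' @param tol normalization tolerance.
#' @return scalar molar mass in kg/mol.
#' @examples
#' st <- species_table(c(a = 0.018, b = 0.180))
#' phase_molecular_weight(c(a = 0.5, b = 0.5), st)
#' @export
phase_molecular_weight <- function(mass_fractions, species, tol = 1e-10) {
  omega <- check_mass_fractions(mass_fractions, tol)
  mw <- species$molar_mass[names(omega)]
  if (anyNA(mw)) stop("unknown species: ",
                      paste(names(omega)[is.na(mw)], collapse = ", "))
  1 / sum(omega / mw)
}

#' Mole fractions from mass fractions
#'
#' `x_i = (omega_i / MW_i) / sum_j(omega_j / MW_j)`.
#'
#' @inheritParams phase_molecular_weight
#' @return named numeric vector of mole fractions summing to 1.
#' @export
mole_fractions <- function(mass_fractions, species, tol = 1e-10) {
  omega <- check_mass_fractions(mass_fractions, tol)
  mw <- species$molar_mass[names(omega)]
  if (anyNA(mw)) stop("unknown species: ",
                      paste(names(omega)[is.na(mw)], collapse = ", "))
  moles <- omega / mw
  total <- sum(moles)
  if (total <= 0) stop("zero total moles")
  moles / total
}

#' Mass fractions from mole fractions
#'
#' Inverse of [mole_fractions()]: `omega_i = MW_i x_i / sum_j MW_j x_j`.
#'
#' @param mole_fractions named numeric vector summing to 1.
#' @param species a [species_table()].
#' @return named numeric vector of mass fractions.
#' @export
mass_fractions <- function(mole_fractions, species) {
  mw <- species$molar_mass[names(mole_fractions)]
  if (anyNA(mw)) stop("unknown species")
  m <- mole_fractions * mw
  m / sum(m)
}

#' Macroscale chemical potential
#'
#' Ideal-solution chemical potential per unit mass,
#' `mu = mu0 + (R_g * theta / MW) * log(x + x_floor)`,
#' with unit activity coefficients.  The mole-fraction floor keeps the
#' potential finite and smooth for vanishing species without perturbing mass balances.
#'
#' @param species species symbol.
#' @param phase phase symbol (used to look up `mu0`).
#' @param mole_fraction mole fraction in \[0, 1\].
#' @param thermo a [thermo_params()].
#' @param species_tab a [species_table()].
#' @return chemical potential in J/kg.
#' @export
chemical_potential <- function(species, phase, mole_fraction, thermo,
                               species_tab) {
  if (any(mole_fraction < 0 | mole_fraction > 1 + 1e-12))
    stop("mole_fraction outside [0, 1]")
  mw <- species_tab$molar_mass[[species]]
  mu0 <- mu0_for(thermo, phase, species)[[species]]
  mu0 + thermo$gas_constant * thermo$temperature / mw *
    log(mole_fraction + thermo$x_floor)
}

## Vectorized potentials for all members of a phase, from mass fractions.
phase_potentials <- function(omega, phase, thermo, species_tab, tol = 1e-10) {
  x <- mole_fractions(omega, species_tab, tol)
  mw <- species_tab$molar_mass[names(x)]
  mu0 <- mu0_for(thermo, phase, names(x))
  mu0 + thermo$gas_constant * thermo$temperature / mw *
    log(x + thermo$x_floor)
}

#' Phase composition state
#'
#' Macroscale state of a set of phases: volume fractions, intrinsic mass
#' densities, species mass fractions, pressures, velocities, and the (single,
#' species-shared) body-force potential per phase.
#'
#' @param phases named list; each element a list with fields
#'   `volume_fraction`, `density`, `mass_fractions` (named numeric),
#'   `pressure`, `velocity`, `body_potential`.
#' @param tol tolerance on the volume-fraction and mass-fraction closures.
#' @return object of class `composition_state`.
#' @export
composition_state <- function(phases, tol = 1e-10) {
  eps <- vapply(phases, function(p) p$volume_fraction, numeric(1))
  if (any(eps < -1e-12 | eps > 1 + 1e-12))
    stop("volume fractions outside [0, 1]")
  if (abs(sum(eps) - 1) > 1e-12)
    stop("volume fractions do not sum to 1: sum = ",
         format(sum(eps), digits = 16))
  for (id in names(phases)) {
    p <- phases[[id]]
    phases[[id]]$mass_fractions <- check_mass_fractions(p$mass_fractions, tol)
    if (is.null(p$velocity)) phases[[id]]$velocity <- 0
    if (is.null(p$body_potential)) phases[[id]]$body_potential <- 0
  }
  structure(list(phases = phases), class = "composition_state")
}

#' @export
print.composition_state <- function(x, ...) {
  cat("<composition_state> phases:",
      paste(names(x$phases), collapse = ", "), "\n")
  for (id in names(x$phases)) {
    p <- x$phases[[id]]
    cat(sprintf("  %s: eps=%.4g rho=%.4g p=%.4g\n", id,
                p$volume_fraction, p$density, p$pressure))
  }
  invisible(x)
}
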