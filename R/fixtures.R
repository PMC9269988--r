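## Built-in scenario generators: the avascular-spheroid study scenario and
## reduced configurations (diffusion-only, transfer-only, reaction-only)
## used for verification.

#' Default reference-state chemical potentials for the tumor models
#'
#' The mu0 ladder makes the biologically forward direction of each channel
#' spontaneous under the linear affinity closure: tumor formation from
#' glucose + oxygen, drug-mediated destruction, oxygen-gated necrosis, and
#' necrotic lysis all carry negative affinity at representative
#' compositions.  Values are per-phase constants (isothermal,
#' incompressible-liquid assumption); see the methods vignette for the
#' scale analysis.
#'
#' @param phase_ids phase symbols to populate.
#' @return named list per phase of named mu0 vectors (J/kg).
#' @export
default_mu0 <- function(phase_ids = c("f", "s")) {
  base <- c(l = -1e6, n = -1.05e6, e = -2.5e6, g = 0, o = 0, c = 0,
            w = -3.3e5, x = 0, y = 0, z = 0)
  out <- lapply(phase_ids, function(ph) base)
  names(out) <- phase_ids
  out
}

#' Default two-phase tumor reaction network
#'
#' The four channels of the solid-phase reaction table, with one free
#' stoichiometric coefficient per reaction solved from the mass balance
#' (`t` of the schemata is the living tumor species `l`):
#' formation `g + 6 o -> nu l`, destruction `l + 0.1 c -> 1.5 e + nu w`,
#' necrosis `l -> n` (gated by the oxygen switch), lysis `n -> e + nu w`.
#'
#' @param species a [species_table()].
#' @param phase phase carrying the reactions (`"s"` two-phase, `"n"`
#'   three-phase).
#' @param k_growth,k_destruction,k_necrosis,k_lysis nonnegative rate
#'   coefficients.
#' @param oxygen_gate `NULL` to disable the necrosis channel's oxygen
#'   switch (the channel is then off), or a function from [oxygen_switch()].
#' @return list of [reaction_spec()].
#' @export
tumor_reactions <- function(species, phase = "s",
                            k_growth = 2e-9, k_destruction = 0,
                            k_necrosis = 5e-8, k_lysis = 5e-9,
                            oxygen_gate = oxygen_switch()) {
  rx <- list()
  st <- balance_stoichiometry(c(g = -1, o = -6, l = NA), "l", species)
  rx$growth <- reaction_spec("growth", phase, st, k_growth,
                             modulation = reactant_limiter(c("g", "o"),
                                                           scale = 1e-5))
  if (k_destruction > 0) {
    st <- balance_stoichiometry(c(l = -1, c = -0.1, e = 1.5, w = NA), "w",
                                species)
    rx$destruction <- reaction_spec(
      "destruction", phase, st, k_destruction,
      modulation = compose_modulation(reactant_limiter("l", scale = 1e-3),
                                      reactant_limiter("c", scale = 1e-5)))
  }
  if (!is.null(oxygen_gate) && k_necrosis > 0) {
    rx$necrosis <- reaction_spec(
      "necrosis", phase, c(l = -1, n = 1), k_necrosis,
      modulation = compose_modulation(oxygen_gate,
                                      reactant_limiter("l", scale = 1e-3)))
  }
  st <- balance_stoichiometry(c(n = -1, e = 1, w = NA), "w", species)
  rx$lysis <- reaction_spec("lysis", phase, st, k_lysis,
                            modulation = reactant_limiter("n", scale = 1e-4))
  unname(rx)
}

#' Avascular-spheroid scenario
#'
#' Spherically symmetric two-phase scenario: ECM + tumor solid bathed in
#' interstitial fluid, nutrients (glucose, oxygen) held at the outer
#' boundary, an initial living-tumor mass-fraction bump at the center, and
#' the four-channel solid reaction network with mass-balanced
#' stoichiometry.  Deterministic given `seed` (the seed perturbs the bump
#' amplitude reproducibly and is recorded in the result).
#'
#' @param radius_m outer radius (m).
#' @param n_cells number of radial cells (>= 8).
#' @param nutrient_boundary_values named vector of fluid boundary mass
#'   fractions held fixed (default glucose and oxygen).
#' @param seed integer seed.
#' @param drug if `TRUE`, enables the chemotherapeutic pathway: drug at the
#'   boundary, fluid/solid drug transfer, and the destruction reaction.
#' @param oxygen_gate if `TRUE`, the necrosis channel runs through the
#'   oxygen-starvation switch; if `FALSE` the channel is off.
#' @param bump_amplitude center peak of the living-tumor mass fraction.
#' @return a [scenario_2p()].
#' @export
build_spheroid_fixture <- function(radius_m = 5e-3, n_cells = 16,
                                   nutrient_boundary_values =
                                     c(g = 1e-3, o = 5e-5),
                                   seed = 1, drug = FALSE,
                                   oxygen_gate = TRUE,
                                   bump_amplitude = 0.15) {
  if (radius_m <= 0) stop("radius must be positive")
  if (n_cells < 8) stop("n_cells must be at least 8")
  species <- default_species_table("2p")
  phases <- default_phase_defs("2p")
  bad <- setdiff(names(nutrient_boundary_values), phases$f$members)
  if (length(bad))
    stop("boundary values for non-fluid species: ", paste(bad, collapse = ", "))
  set.seed(seed)
  amp <- bump_amplitude * (1 + 0.05 * stats::runif(1, -1, 1))
  g <- uniform_grid(n_cells, radius_m, "spherical")
  thermo <- thermo_params(temperature = 310,
                          mu0 = default_mu0(c("f", "s")), x_floor = 1e-8)
  n <- g$n
  r0 <- radius_m / 4
  bump <- amp * exp(-(g$centers / r0)^2)
  omega_s <- matrix(0, n, length(phases$s$members),
                    dimnames = list(NULL, phases$s$members))
  omega_s[, "l"] <- 0.05 + bump
  omega_s[, "n"] <- 0
  omega_s[, "g"] <- 1e-3
  omega_s[, "o"] <- 5e-5
  omega_s[, "c"] <- 0
  omega_s[, "w"] <- 0.10
  omega_s[, "y"] <- 0.20
  omega_s[, "e"] <- 1 - rowSums(omega_s)
  omega_f <- matrix(0, n, length(phases$f$members),
                    dimnames = list(NULL, phases$f$members))
  omega_f[, "g"] <- nutrient_boundary_values[["g"]]
  omega_f[, "o"] <- nutrient_boundary_values[["o"]]
  omega_f[, "c"] <- if (drug) 1e-4 else 0
  omega_f[, "x"] <- 0.05
  omega_f[, "w"] <- 1 - rowSums(omega_f)
  transfers <- list(
    transfer_spec("g", "f", "s", 1e-6),
    transfer_spec("o", "f", "s", 1e-6),
    transfer_spec("w", "f", "s", 1e-7))
  if (drug) transfers <- c(transfers, list(transfer_spec("c", "f", "s", 1e-6)))
  reactions <- tumor_reactions(
    species, "s",
    k_growth = 2e-9,
    k_destruction = if (drug) 2e-9 else 0,
    k_necrosis = 5e-8,
    k_lysis = 5e-9,
    oxygen_gate = if (oxygen_gate) oxygen_switch() else NULL)
  bc_species <- lapply(names(nutrient_boundary_values), function(sp)
    list(type = "dirichlet", value = nutrient_boundary_values[[sp]]))
  names(bc_species) <- names(nutrient_boundary_values)
  if (drug) bc_species$c <- list(type = "dirichlet", value = 1e-4)
  scenario_2p(
    grid = g, species = species, phases = phases, thermo = thermo,
    densities = c(f = 1000, s = 1050),
    reactions = reactions, transfers = transfers,
    coeffs = closure_coeffs(
      diffusivity = list(f = c(g = 7e-10, o = 2e-9, c = 5e-10, x = 1e-10),
                         s = c(g = 1e-10, o = 5e-10, c = 1e-10)),
      resistance = list(f = 1e9)),
    initial = list(eps_s = rep(0.3, n), omega_f = omega_f,
                   omega_s = omega_s),
    bc = list(pressure = list(outer = 0, inner = NA), species = bc_species),
    solver = list(rtol = 1e-6, atol = 1e-10, method = "vode"),
    seed = seed)
}

#' Dilute-solute diffusion scenario
#'
#' Single inert solute in a quiescent fluid on a Cartesian grid: no
#' reactions, no transfer, uniform pressure; the chemical-potential
#' diffusion closure degenerates to Fickian diffusion with coefficient `d`
#' in the dilute limit, against which the analytic Gaussian kernel is an
#' oracle.
#'
#' @param n_cells number of cells.
#' @param length domain length (m).
#' @param d solute diffusivity (m^2/s).
#' @param amplitude peak solute mass fraction (keep dilute).
#' @param sigma0 initial Gaussian standard deviation (m).
#' @return a [scenario_2p()].
#' @export
build_diffusion_fixture <- function(n_cells = 128, length = 4e-2,
                                    d = 1e-9, amplitude = 1e-4,
                                    sigma0 = 1e-3) {
  species <- species_table(c(g = 0.180, w = 0.018, e = 0.5))
  phases <- list(
    f = phase_def("f", c("g", "w"), "w", species),
    s = phase_def("s", "e", "e", species))
  g <- uniform_grid(n_cells, length, "cartesian")
  n <- g$n
  x0 <- length / 2
  omega_g <- amplitude * exp(-(g$centers - x0)^2 / (2 * sigma0^2))
  omega_f <- cbind(g = omega_g, w = 1 - omega_g)
  omega_s <- matrix(1, n, 1, dimnames = list(NULL, "e"))
  scenario_2p(
    grid = g, species = species, phases = phases,
    thermo = thermo_params(temperature = 310),
    densities = c(f = 1000, s = 1050),
    coeffs = closure_coeffs(diffusivity = list(f = c(g = d)),
                            resistance = list(f = 1e9)),
    initial = list(eps_s = rep(0.5, n), omega_f = omega_f,
                   omega_s = omega_s),
    bc = list(pressure = list(outer = NA, inner = NA), gauge_cell = 1,
              species = list()),
    solver = list(rtol = 1e-9, atol = 1e-13, method = "lsodes"))
}

#' Well-mixed transfer-only scenario (one cell)
#'
#' Fluid/solid exchange of a single solute with everything else frozen; the
#' two-compartment limit has a closed-form balance against which the full
#' simulator and the coefficient-recovery routine are checked.
#'
#' @param k_m transfer coefficient.
#' @param omega_f0,omega_s0 initial solute mass fractions.
#' @return a [scenario_2p()].
#' @export
build_transfer_fixture <- function(k_m = 1e-7, omega_f0 = 5e-4,
                                   omega_s0 = 5e-3) {
  species <- species_table(c(o = 0.032, w = 0.018, e = 0.5))
  phases <- list(
    f = phase_def("f", c("o", "w"), "w", species),
    s = phase_def("s", c("o", "e"), "e", species))
  g <- uniform_grid(1, 1e-3, "cartesian")
  omega_f <- cbind(o = omega_f0, w = 1 - omega_f0)
  omega_s <- cbind(o = omega_s0, e = 1 - omega_s0)
  scenario_2p(
    grid = g, species = species, phases = phases,
    thermo = thermo_params(temperature = 310),
    densities = c(f = 1000, s = 1000),
    transfers = list(transfer_spec("o", "f", "s", k_m)),
    coeffs = closure_coeffs(resistance = list(f = 1e9)),
    initial = list(eps_s = rep(0.5, 1), omega_f = omega_f,
                   omega_s = omega_s),
    bc = list(pressure = list(outer = NA, inner = NA), gauge_cell = 1,
              species = list()),
    solver = list(rtol = 1e-9, atol = 1e-13, method = "lsoda"))
}

#' Well-mixed reaction-only scenario (one cell)
#'
#' A single mass-balanced isomerization `l -> n` in the solid phase with
#' transfers frozen, used for kinetics verification and rate-coefficient
#' recovery.
#'
#' @param k rate coefficient.
#' @param omega_l0 initial living-tumor mass fraction.
#' @return a [scenario_2p()].
#' @export
build_reaction_fixture <- function(k = 1e-7, omega_l0 = 0.2) {
  species <- species_table(c(l = 1, n = 1, e = 0.5, w = 0.018))
  phases <- list(
    f = phase_def("f", "w", "w", species),
    s = phase_def("s", c("l", "n", "e"), "e", species))
  g <- uniform_grid(1, 1e-3, "cartesian")
  mu0 <- list(s = c(l = -1e6, n = -1.05e6, e = -2.5e6))
  omega_s <- cbind(l = omega_l0, n = 1e-3, e = 1 - omega_l0 - 1e-3)
  scenario_2p(
    grid = g, species = species, phases = phases,
    thermo = thermo_params(temperature = 310, mu0 = mu0),
    densities = c(f = 1000, s = 1050),
    reactions = list(reaction_spec("necrosis", "s", c(l = -1, n = 1), k)),
    coeffs = closure_coeffs(resistance = list(f = 1e9)),
    initial = list(eps_s = rep(0.5, 1),
                   omega_f = matrix(1, 1, 1, dimnames = list(NULL, "w")),
                   omega_s = omega_s),
    bc = list(pressure = list(outer = NA, inner = NA), gauge_cell = 1,
              species = list()),
    solver = list(rtol = 1e-9, atol = 1e-13, method = "lsoda"))
}

#' Constructed two-phase equilibrium scenario
#'
#' Reference potentials are tuned so that every species has equal chemical
#' potential within and across phases at the initial composition: all
#' affinities vanish, all transfer driving forces vanish, the pressure is
#' uniform, and the state is a fixed point of the simulator.
#'
#' @param n_cells number of cells.
#' @return a [scenario_2p()].
#' @export
build_equilibrium_fixture <- function(n_cells = 4) {
  species <- species_table(c(o = 0.032, g = 0.180, w = 0.018, e = 0.5))
  phases <- list(
    f = phase_def("f", c("o", "g", "w"), "w", species),
    s = phase_def("s", c("o", "g", "e"), "e", species))
  g <- uniform_grid(n_cells, 1e-3, "cartesian")
  n <- g$n
  om_f <- c(o = 1e-4, g = 1e-3, w = 1 - 1e-4 - 1e-3)
  om_s <- c(o = 2e-4, g = 5e-4, e = 1 - 2e-4 - 5e-4)
  th0 <- thermo_params(temperature = 310)
  ## pin every potential to the same constant C
  C <- -1e4
  mu0 <- list(
    f = C - phase_potentials(om_f, "f", th0, species),
    s = C - phase_potentials(om_s, "s", th0, species))
  thermo <- thermo_params(temperature = 310, mu0 = mu0)
  scenario_2p(
    grid = g, species = species, phases = phases, thermo = thermo,
    densities = c(f = 1000, s = 1050),
    reactions = list(
      reaction_spec("iso", "s",
                    balance_stoichiometry(c(g = -1, o = NA), "o", species),
                    1e-6)),
    transfers = list(transfer_spec("o", "f", "s", 1e-6),
                     transfer_spec("g", "f", "s", 1e-6)),
    coeffs = closure_coeffs(
      diffusivity = list(f = c(o = 1e-9, g = 1e-9)),
      resistance = list(f = 1e9)),
    initial = list(
      eps_s = rep(0.4, n),
      omega_f = matrix(om_f, n, 3, byrow = TRUE,
                       dimnames = list(NULL, names(om_f))),
      omega_s = matrix(om_s, n, 3, byrow = TRUE,
                       dimnames = list(NULL, names(om_s)))),
    bc = list(pressure = list(outer = 0, inner = NA), species = list()),
    solver = list(rtol = 1e-10, atol = 1e-14, method = "lsoda"))
}
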