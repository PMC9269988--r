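## Well-mixed (0-D) three-phase dynamical system: wetting fluid, tumor-cell
## (non-wetting) fluid, solid scaffold; compositions by affinity kinetics
## and potential-driven transfer, geometry by the interfacial-area and
## curvature evolution equations, capillary pressure by inverting the
## capillary relaxation closure.

#' Three-phase well-mixed scenario configuration
#'
#' @param species a [species_table()] (ten-species set).
#' @param phases named list of [phase_def()] with elements `w`, `n`, `s`.
#' @param thermo a [thermo_params()].
#' @param density common phase mass density (kg/m^3).  A well-mixed closed
#'   volume conserves `sum(eps) = 1` under transfer only when the phase
#'   densities are equal; the spatially resolved model relaxes this.
#' @param reactions list of [reaction_spec()] (non-wetting phase).
#' @param transfers list of [transfer_spec()] over the three phase pairs.
#' @param coeffs a [closure_coeffs()] (uses `tension["wn"]`,
#'   `area_relaxation`, `capillary_relaxation`, `compressibility`).
#' @param initial list with `eps` (`c(w=,n=,s=)`), `omega` (named list of
#'   named vectors per phase), `geometry` (a [geometry_state()]).
#' @param eps_eq_fun equilibrium interfacial area as a function of wetting
#'   saturation `s_w = eps_w / (eps_w + eps_n)`; default quadratic bump
#'   `a s_w (1 - s_w)` with `a` chosen so the initial state is attainable.
#' @param p_n reference non-wetting pressure (Pa).
#' @param body_potential named numeric per phase (J/kg).
#' @param solver list with `rtol`, `atol`, `method`.
#' @param seed recorded seed.
#' @return object of class `scenario_3p`.
#' @export
scenario_3p <- function(species, phases, thermo, density = 1000,
                        reactions = list(), transfers = list(),
                        coeffs = closure_coeffs(),
                        initial, eps_eq_fun = NULL, p_n = 0,
                        body_potential = c(w = 0, n = 0, s = 0),
                        solver = list(rtol = 1e-10, atol = 1e-13,
                                      method = "lsoda"),
                        seed = NA_integer_) {
  if (!all(c("w", "n", "s") %in% names(phases)))
    stop("three-phase scenarios need phases 'w', 'n', 's'")
  for (rx in reactions) {
    v <- validate_reaction(rx, species)
    if (!v$ok) stop(v$message)
    bad <- setdiff(names(rx$stoich), phases[[rx$phase]]$members)
    if (length(bad))
      stop("reaction '", rx$id, "' involves species not in phase '",
           rx$phase, "': ", paste(bad, collapse = ", "))
  }
  for (tr in transfers) {
    for (ph in c(tr$donor, tr$receiver))
      if (!tr$species %in% phases[[ph]]$members)
        stop("transfer species '", tr$species, "' not shared by phases '",
             tr$donor, "'/'", tr$receiver, "'")
  }
  if (abs(sum(initial$eps) - 1) > 1e-12)
    stop("initial volume fractions must sum to 1")
  if (is.null(eps_eq_fun)) {
    a <- 4 * initial$geometry$areas[["wn"]] /
      max(4 * {
        s0 <- initial$eps[["w"]] / (initial$eps[["w"]] + initial$eps[["n"]])
        s0 * (1 - s0)
      }, 1e-12)
    ## default: quadratic bump through the initial state
    eps_eq_fun <- local({
      a_loc <- a
      function(s_w) a_loc * s_w * (1 - s_w)
    })
  }
  if (is.null(solver$rtol)) solver$rtol <- 1e-10
  if (is.null(solver$atol)) solver$atol <- 1e-13
  if (is.null(solver$method)) solver$method <- "lsoda"
  structure(list(species = species, phases = phases, thermo = thermo,
                 density = density, reactions = reactions,
                 transfers = transfers, coeffs = coeffs, initial = initial,
                 eps_eq_fun = eps_eq_fun, p_n = p_n,
                 body_potential = body_potential, solver = solver,
                 seed = seed),
            class = "scenario_3p")
}

pack_state_3p <- function(config, eps, omega, eps_wn, K) {
  y <- c(eps[["w"]], eps[["n"]])
  for (ph in c("w", "n", "s")) {
    pd <- config$phases[[ph]]
    y <- c(y, omega[[ph]][members_nonref(pd)])
  }
  c(y, eps_wn, K)
}

unpack_state_3p <- function(config, y) {
  eps <- c(w = y[1], n = y[2], s = 1 - y[1] - y[2])
  off <- 2
  omega <- list()
  for (ph in c("w", "n", "s")) {
    pd <- config$phases[[ph]]
    nr <- members_nonref(pd)
    om <- stats::setNames(y[off + seq_along(nr)], nr)
    off <- off + length(nr)
    om[pd$reference_species] <- 1 - sum(om)
    omega[[ph]] <- om[pd$members]
  }
  list(eps = eps, omega = omega, eps_wn = y[off + 1], K = y[off + 2])
}

rhs_3p <- function(config, y, with_extras = FALSE) {
  st <- unpack_state_3p(config, y)
  if (any(st$eps < -1e-8 | st$eps > 1 + 1e-8))
    stop("phase volume fraction left [0, 1]: eps = (",
         paste(format(st$eps, digits = 6), collapse = ", "), ")")
  rho <- config$density
  thermo <- config$thermo; species <- config$species
  mu <- list()
  for (ph in c("w", "n", "s")) {
    om <- pmax(st$omega[[ph]], 0)
    mu[[ph]] <- phase_potentials(om / sum(om), ph, thermo, species,
                                 tol = Inf)
  }
  psi <- config$body_potential
  ## species mass tendencies per phase (kg/(m^3 s))
  dm <- lapply(config$phases, function(pd)
    stats::setNames(numeric(length(pd$members)), pd$members))
  for (tr in config$transfers) {
    delta <- (mu[[tr$donor]][[tr$species]] + psi[[tr$donor]]) -
      (mu[[tr$receiver]][[tr$species]] + psi[[tr$receiver]])
    M <- tr$transfer_coeff * delta
    dm[[tr$donor]][[tr$species]] <- dm[[tr$donor]][[tr$species]] - M
    dm[[tr$receiver]][[tr$species]] <- dm[[tr$receiver]][[tr$species]] + M
  }
  aff <- numeric(length(config$reactions))
  keff <- numeric(length(config$reactions))
  for (k in seq_along(config$reactions)) {
    rx <- config$reactions[[k]]
    A <- affinity(rx, mu[[rx$phase]], species)
    ke <- effective_rate_coeff(rx, st$omega[[rx$phase]])
    R <- -ke * A
    mw <- species$molar_mass[names(rx$stoich)]
    contrib <- st$eps[[rx$phase]] * rx$stoich * mw * R
    dm[[rx$phase]][names(contrib)] <- dm[[rx$phase]][names(contrib)] + contrib
    aff[k] <- A; keff[k] <- ke
  }
  deps <- vapply(dm, sum, numeric(1)) / rho
  domega <- list()
  for (ph in c("w", "n", "s")) {
    e <- max(st$eps[[ph]], 1e-12)
    domega[[ph]] <- (dm[[ph]] - st$omega[[ph]] * rho * deps[[ph]]) / (e * rho)
  }
  ## geometry
  geo <- config$initial$geometry
  s_w <- st$eps[["w"]] / (st$eps[["w"]] + st$eps[["n"]])
  eps_eq <- config$eps_eq_fun(s_w)
  J0 <- config$initial$geometry$J_w_wn; K0 <- config$initial$geometry$K_n_wn
  J <- if (K0 > 0) J0 * sqrt(st$K / K0) else J0
  gs <- geometry_state(
    eps = st$eps,
    areas = c(wn = st$eps_wn, ws = geo$areas[["ws"]],
              ns = geo$areas[["ns"]]),
    J_w_wn = J, K_n_wn = st$K, K_n_ns = geo$K_n_ns,
    chi_n = geo$chi_n, chi_s_ws = geo$chi_s_ws, J_s_ss = geo$J_s_ss,
    contact_angle = geo$contact_angle)
  deps_wn <- interfacial_area_rate(
    gs, deps_w_dt = deps[["w"]], deps_s_dt = deps[["s"]], dchi_dt = 0,
    eps_eq = eps_eq, k_wn = config$coeffs$area_relaxation)
  dK <- curvature_rate_0d(gs, deps_wn)
  dy <- pack_state_3p(config, deps, domega, deps_wn, dK)
  if (!with_extras) return(list(dy = dy))
  ## capillary pressure from the inverted relaxation closure
  dporo <- deps[["w"]] + deps[["n"]]
  L <- deps[["w"]] - gs$chi_s_ws * dporo
  gamma_wn <- if ("wn" %in% names(config$coeffs$tension))
    config$coeffs$tension[["wn"]] else 0
  p_c <- if (config$coeffs$capillary_relaxation > 0)
    invert_capillary_pressure(L, gamma_wn, J,
                              config$coeffs$capillary_relaxation)
  else gamma_wn * J
  list(dy = dy,
       extras = list(mu = mu, affinity = aff, keff = keff,
                     deps = deps, geometry = gs, p_c = p_c,
                     p_w = config$p_n + p_c, p_n = config$p_n,
                     eps_eq = eps_eq))
}

#' Integrate the well-mixed three-phase model
#'
#' Per step: transfer and reaction mass balances determine the composition
#' and volume-fraction rates; the capillary pressure follows by inverting
#' the capillary relaxation closure at the mass-balance-determined rates;
#' the fluid-fluid interfacial area evolves by its geometric evolution
#' equation and the Gaussian curvature by conservation of `eps_wn K`.  The
#' entropy ledger is recorded at every output time.
#'
#' @param config a [scenario_3p()].
#' @param times output times (s).
#' @return object of class `sim_result_3p` with `times`, per-time `states`
#'   (unpacked), `diagnostics` (ledger, capillary pressure, masses).
#' @export
simulate3p0d <- function(config, times) {
  y0 <- pack_state_3p(config, config$initial$eps, config$initial$omega,
                      config$initial$geometry$areas[["wn"]],
                      config$initial$geometry$K_n_wn)
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, p) list(rhs_3p(config, y)$dy),
                      parms = NULL, method = config$solver$method,
                      rtol = config$solver$rtol, atol = config$solver$atol)
  if (attr(sol, "istate")[1] < 0)
    stop("three-phase integration failed; last time reached: ",
         max(sol[, 1]))
  nt <- nrow(sol)
  states <- vector("list", nt)
  diags <- vector("list", nt)
  rho <- config$density
  for (it in seq_len(nt)) {
    st <- unpack_state_3p(config, sol[it, -1])
    ex <- rhs_3p(config, sol[it, -1], with_extras = TRUE)$extras
    masses <- lapply(c(w = "w", n = "n", s = "s"), function(ph)
      st$eps[[ph]] * rho * st$omega[[ph]])
    ledger <- audit_three_phase(
      state = list(eps = as.list(st$eps), rho = list(w = rho, n = rho,
                                                     s = rho),
                   omega = lapply(st$omega, function(o) {
                     o <- pmax(o, 0); o / sum(o)
                   }),
                   body_potential = config$body_potential),
      geometry = ex$geometry, coeffs = config$coeffs,
      thermo = config$thermo, species = config$species,
      phases = config$phases, reactions = config$reactions,
      transfers = config$transfers,
      p_w = ex$p_w, p_n = ex$p_n)
    states[[it]] <- c(st, list(J = ex$geometry$J_w_wn))
    diags[[it]] <- list(ledger = ledger, p_c = ex$p_c,
                        masses = masses, eps_eq = ex$eps_eq)
  }
  structure(list(times = sol[, 1], states = states, diagnostics = diags,
                 config = config, seed = config$seed),
            class = "sim_result_3p")
}

#' @export
print.sim_result_3p <- function(x, ...) {
  cat(sprintf("<sim_result_3p> %d output times over [%g, %g] s\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Well-mixed three-phase tumor fixture
#'
#' Deterministic (seeded) scenario: tumor-cell fluid spheres in a wetting
#' interstitial bath within a solid scaffold, the four-channel reaction
#' network in the non-wetting phase, nutrient transfer across the three
#' phase pairs, and sphere-pack initial geometry.  In this phase split the
#' destruction and lysis products report to the non-wetting background
#' species (dissolved debris) so that every reaction stays within the
#' phase's member set.
#'
#' @param seed integer seed.
#' @param drug enable the chemotherapy channel.
#' @param oxygen_gate gate necrosis on oxygen starvation (`FALSE` disables
#'   the channel).
#' @return a [scenario_3p()].
#' @export
build_threephase_fixture <- function(seed = 1, drug = FALSE,
                                     oxygen_gate = TRUE) {
  species <- default_species_table("3p")
  phases <- default_phase_defs("3p")
  set.seed(seed)
  mu0_n <- default_mu0("n")$n
  mu0_n[["x"]] <- -8e6   # debris species: keeps destruction/lysis downhill
  thermo <- thermo_params(
    temperature = 310,
    mu0 = list(w = default_mu0("w")$w, n = mu0_n, s = default_mu0("s")$s))
  omega <- list(
    w = c(g = 1e-3, o = 5e-5, c = if (drug) 1e-4 else 0, z = 0.05,
          w = NA),
    n = c(l = NA, n = 1e-6, g = 1e-3, o = 5e-5, c = 0, w = 0.20,
          x = 0.05),
    s = c(e = NA, g = 1e-3, o = 5e-5, w = 0.10, y = 0.20))
  omega$w[["w"]] <- 1 - sum(omega$w, na.rm = TRUE)
  omega$n[["l"]] <- 1 - sum(omega$n, na.rm = TRUE)
  omega$s[["e"]] <- 1 - sum(omega$s, na.rm = TRUE)
  rx <- list()
  rx[[1]] <- reaction_spec(
    "growth", "n", balance_stoichiometry(c(g = -1, o = -6, l = NA), "l",
                                         species), 1e-7,
    modulation = reactant_limiter(c("g", "o")))
  if (drug)
    rx[[length(rx) + 1]] <- reaction_spec(
      "destruction", "n",
      balance_stoichiometry(c(l = -1, c = -0.1, x = 1, w = NA), "w",
                            species), 5e-8,
      modulation = reactant_limiter(c("l", "c")))
  if (oxygen_gate)
    rx[[length(rx) + 1]] <- reaction_spec(
      "necrosis", "n", c(l = -1, n = 1), 1e-7,
      modulation = compose_modulation(oxygen_switch(), reactant_limiter("l")))
  rx[[length(rx) + 1]] <- reaction_spec(
    "lysis", "n", balance_stoichiometry(c(n = -1, x = 1, w = NA), "w",
                                        species), 1e-8,
    modulation = reactant_limiter("n"))
  transfers <- list(
    transfer_spec("g", "w", "n", 1e-6),
    transfer_spec("o", "w", "n", 1e-6),
    transfer_spec("w", "w", "n", 1e-7),
    transfer_spec("g", "w", "s", 2e-7),
    transfer_spec("o", "w", "s", 2e-7),
    transfer_spec("g", "n", "s", 1e-7),
    transfer_spec("o", "n", "s", 1e-7))
  if (drug) transfers <- c(transfers,
                           list(transfer_spec("c", "w", "n", 1e-6)))
  geometry <- sphere_pack_state(number_density = 2e9, radius = 2e-4,
                                eps_s = 0.3)
  scenario_3p(
    species = species, phases = phases, thermo = thermo, density = 1000,
    reactions = rx, transfers = transfers,
    coeffs = closure_coeffs(
      tension = c(wn = 0.01, ws = 0.01, ns = 0.02),
      area_relaxation = 1e-3, capillary_relaxation = 1e-6),
    initial = list(eps = geometry$eps, omega = omega, geometry = geometry),
    p_n = 0, seed = seed)
}

#' Constructed three-phase equilibrium scenario
#'
#' Equal augmented potentials across and within phases, zero affinities,
#' interfacial area at its equilibrium value and Young-Laplace-consistent
#' capillary pressure: a fixed point of [simulate3p0d()].
#'
#' @return a [scenario_3p()].
#' @export
build_equilibrium_fixture_3p <- function() {
  species <- default_species_table("3p")
  phases <- default_phase_defs("3p")
  omega <- list(
    w = c(g = 1e-3, o = 1e-4, c = 1e-5, z = 0.05, w = NA),
    n = c(l = 0.3, n = 1e-4, g = 5e-4, o = 5e-5, c = 5e-6, w = 0.2,
          x = NA),
    s = c(e = NA, g = 2e-4, o = 2e-5, w = 0.1, y = 0.2))
  omega$w[["w"]] <- 1 - sum(omega$w, na.rm = TRUE)
  omega$n[["x"]] <- 1 - sum(omega$n, na.rm = TRUE)
  omega$s[["e"]] <- 1 - sum(omega$s, na.rm = TRUE)
  th0 <- thermo_params(temperature = 310)
  C <- -1e4
  mu0 <- lapply(names(phases), function(ph)
    C - phase_potentials(omega[[ph]], ph, th0, species))
  names(mu0) <- names(phases)
  thermo <- thermo_params(temperature = 310, mu0 = mu0)
  geometry <- sphere_pack_state(number_density = 2e9, radius = 2e-4,
                                eps_s = 0.3)
  rx <- list(reaction_spec(
    "iso", "n", balance_stoichiometry(c(g = -1, o = NA), "o", species),
    1e-7))
  transfers <- list(transfer_spec("g", "w", "n", 1e-6),
                    transfer_spec("o", "w", "n", 1e-6),
                    transfer_spec("o", "n", "s", 1e-7))
  eps_eq_fun <- local({
    target <- geometry$areas[["wn"]]
    function(s_w) target
  })
  scenario_3p(
    species = species, phases = phases, thermo = thermo, density = 1000,
    reactions = rx, transfers = transfers,
    coeffs = closure_coeffs(tension = c(wn = 0.01),
                            area_relaxation = 1e-3,
                            capillary_relaxation = 1e-6),
    initial = list(eps = geometry$eps, omega = omega, geometry = geometry),
    eps_eq_fun = eps_eq_fun, p_n = 0)
}
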