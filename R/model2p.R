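## Closed two-phase (interstitial fluid + tissue solid) compositional model
## on 1-D finite-volume grids: quasi-static Darcy-type flow, chemical-
## potential diffusion, affinity kinetics, interphase mass transfer.

#' Two-phase scenario configuration
#'
#' Bundles everything needed to integrate the closed two-phase model:
#' grid, species and phase definitions, thermodynamics, kinetics, closure
#' coefficients, initial fields, boundary conditions and solver controls.
#'
#' @param grid a [grid_1d()].
#' @param species a [species_table()].
#' @param phases named list of [phase_def()] with elements `f` and `s`.
#' @param thermo a [thermo_params()].
#' @param densities named numeric `c(f = ..., s = ...)`, kg/m^3
#'   (incompressible phases).
#' @param reactions list of [reaction_spec()] (solid phase).
#' @param transfers list of [transfer_spec()] (fluid/solid pairs).
#' @param coeffs a [closure_coeffs()]; `resistance$f` is the scalar Darcy
#'   resistance of the fluid.
#' @param initial list with `eps_s` (length-n vector) and matrices
#'   `omega_f`, `omega_s` (n rows, member columns, rows summing to 1).
#' @param bc list with `pressure = list(outer = <Pa or NA>, inner = <Pa or
#'   NA>)` (NA meaning no-flux) and `species` (named list, each
#'   `list(type = "dirichlet"|"noflux", value = <mass fraction>)`, applied
#'   to the fluid at the outer boundary), optional `gauge_cell`.
#' @param body_potential named numeric `c(f = ..., s = ...)` (J/kg).
#' @param gravity axial body acceleration (m/s^2).
#' @param solver list with `rtol`, `atol`, `method`.
#' @param seed integer seed recorded in results.
#' @return object of class `scenario_2p`.
#' @export
scenario_2p <- function(grid, species, phases, thermo, densities,
                        reactions = list(), transfers = list(),
                        coeffs = closure_coeffs(),
                        initial, bc = list(), body_potential = c(f = 0, s = 0),
                        gravity = 0,
                        solver = list(rtol = 1e-8, atol = 1e-10,
                                      method = "lsodes"),
                        seed = NA_integer_) {
  stopifnot(inherits(grid, "grid_1d"), inherits(species, "species_table"))
  if (!all(c("f", "s") %in% names(phases)))
    stop("two-phase scenarios need phases 'f' and 's'")
  for (rx in reactions) {
    v <- validate_reaction(rx, species)
    if (!v$ok) stop(v$message)
  }
  n <- grid$n
  if (length(initial$eps_s) != n) stop("initial$eps_s must have one value per cell")
  if (any(initial$eps_s < 0 | initial$eps_s > 1))
    stop("initial eps_s outside [0, 1]")
  for (ph in c("f", "s")) {
    om <- initial[[paste0("omega_", ph)]]
    if (!is.matrix(om) || nrow(om) != n ||
        !setequal(colnames(om), phases[[ph]]$members))
      stop("initial$omega_", ph, " must be an n x members matrix")
    if (max(abs(rowSums(om) - 1)) > 1e-10)
      stop("initial omega_", ph, " rows must sum to 1")
  }
  bad_bc <- setdiff(names(bc$species), phases$f$members)
  if (length(bad_bc))
    stop("boundary condition for non-member fluid species: ",
         paste(bad_bc, collapse = ", "))
  if (is.null(bc$pressure)) bc$pressure <- list(outer = 0, inner = NA)
  if (is.null(bc$pressure$inner)) bc$pressure$inner <- NA
  if (is.null(solver$rtol)) solver$rtol <- 1e-8
  if (is.null(solver$atol)) solver$atol <- 1e-10
  if (is.null(solver$method)) solver$method <- "lsodes"
  structure(list(grid = grid, species = species, phases = phases,
                 thermo = thermo, densities = densities,
                 reactions = reactions, transfers = transfers,
                 coeffs = coeffs, initial = initial, bc = bc,
                 body_potential = body_potential, gravity = gravity,
                 solver = solver, seed = seed),
            class = "scenario_2p")
}

## ---- state packing ---------------------------------------------------

members_nonref <- function(phase) setdiff(phase$members, phase$reference_species)

pack_state_2p <- function(config, eps_s, omega_f, omega_s) {
  nf <- members_nonref(config$phases$f)
  ns <- members_nonref(config$phases$s)
  c(eps_s, as.vector(omega_s[, ns, drop = FALSE]),
    as.vector(omega_f[, nf, drop = FALSE]))
}

unpack_state_2p <- function(config, y) {
  n <- config$grid$n
  fph <- config$phases$f; sph <- config$phases$s
  nf <- members_nonref(fph); ns <- members_nonref(sph)
  eps_s <- y[seq_len(n)]
  off <- n
  om_s <- matrix(y[off + seq_len(n * length(ns))], n, length(ns),
                 dimnames = list(NULL, ns))
  off <- off + n * length(ns)
  om_f <- matrix(y[off + seq_len(n * length(nf))], n, length(nf),
                 dimnames = list(NULL, nf))
  omega_s <- cbind(om_s, 1 - rowSums(om_s))
  colnames(omega_s) <- c(ns, sph$reference_species)
  omega_s <- omega_s[, sph$members, drop = FALSE]
  omega_f <- cbind(om_f, 1 - rowSums(om_f))
  colnames(omega_f) <- c(nf, fph$reference_species)
  omega_f <- omega_f[, fph$members, drop = FALSE]
  list(eps_s = eps_s, eps_f = 1 - eps_s, omega_f = omega_f,
       omega_s = omega_s)
}

## Per-cell chemical potentials for one phase (rows: cells).
potentials_matrix <- function(omega, phase_id, thermo, species) {
  mw <- species$molar_mass[colnames(omega)]
  om <- pmax(omega, 0)
  moles <- sweep(om, 2, mw, "/")
  x <- moles / rowSums(moles)
  mu0 <- mu0_for(thermo, phase_id, colnames(omega))
  rt <- thermo$gas_constant * thermo$temperature
  sweep(sweep(log(x + thermo$x_floor), 2, rt / mw, "*"), 2, mu0, "+")
}

## Transfer rates (fluid -> solid, kg/(m^3 s)) per cell and species.
transfer_matrix_2p <- function(config, mu_f, mu_s) {
  n <- nrow(mu_f)
  shared <- unique(vapply(config$transfers, function(tr) tr$species,
                          character(1)))
  M <- matrix(0, n, length(shared), dimnames = list(NULL, shared))
  psi <- config$body_potential
  for (tr in config$transfers) {
    sp <- tr$species
    delta <- (mu_f[, sp] + psi[["f"]]) - (mu_s[, sp] + psi[["s"]])
    ## antisymmetric: rate fluid->solid has the same closure regardless of
    ## which phase the spec labels as donor
    M[, sp] <- M[, sp] + tr$transfer_coeff * delta
  }
  M
}

## Reaction source terms r^{is} (kg/(m^3 s)) per cell and solid species,
## plus per-cell affinities and effective coefficients for the audit.
reaction_matrix_2p <- function(config, mu_s, omega_s) {
  n <- nrow(mu_s)
  sph <- config$phases$s
  r <- matrix(0, n, length(sph$members), dimnames = list(NULL, sph$members))
  aff <- matrix(0, n, length(config$reactions))
  keff <- matrix(0, n, length(config$reactions))
  for (k in seq_along(config$reactions)) {
    rx <- config$reactions[[k]]
    mw <- config$species$molar_mass[names(rx$stoich)]
    A <- as.vector(mu_s[, names(rx$stoich), drop = FALSE] %*%
                     (rx$stoich * mw))
    ke <- if (is.null(rx$modulation)) rep(rx$rate_coeff, n)
          else rx$rate_coeff * rep_len(rx$modulation(omega_s), n)
    R <- -ke * A
    r[, names(rx$stoich)] <- r[, names(rx$stoich)] +
      outer(R, rx$stoich * mw)
    aff[, k] <- A; keff[, k] <- ke
  }
  list(r = r, affinity = aff, keff = keff)
}

#' Pressure solve for the two-phase model
#'
#' Cell-centered elliptic solve: the Darcy-type velocity
#' `v_f = v_s - eps_f (grad p - rho_f g) / R_f` must make the overall fluid
#' mass balance consistent with the interphase volume source
#' `T (1/rho_s - 1/rho_f)` produced by mass transfer.  Dirichlet pressure
#' values act at domain faces via half-cell two-point fluxes; an all-Neumann
#' problem requires `bc$gauge_cell`.
#'
#' @param state list with `eps_f` (per cell) as produced by the integrator.
#' @param config a [scenario_2p()].
#' @param source_vol per-cell volumetric source (1/s); defaults to zero.
#' @return list with `p` (Pa per cell), `face_flux` (`eps_f v_f` at faces)
#'   and `v_face` (fluid velocity at faces).
#' @export
solve_pressure <- function(state, config, source_vol = NULL) {
  g <- config$grid
  n <- g$n
  if (is.null(source_vol)) source_vol <- rep(0, n)
  eps_f <- state$eps_f
  rho_f <- config$densities[["f"]]
  r_hat <- config$coeffs$resistance$f
  if (is.null(r_hat)) stop("coeffs$resistance$f (fluid Darcy resistance) required")
  kap <- eps_f^2 / r_hat
  dxc <- diff(g$centers)
  kap_face_int <- (kap[-n] + kap[-1]) / 2           # interior faces 2..n
  A <- g$face_areas; V <- g$volumes
  gx <- config$gravity
  lower <- numeric(n - 1); upper <- numeric(n - 1); diagm <- numeric(n)
  rhs <- source_vol * V
  ## interior faces: flux_j = -kap_face * ((p[j+1]-p[j])/dxc - rho g)
  ## divergence for cell k: (A_out*F_out - A_in*F_in) = rhs_k * V_k ... with
  ## F oriented along +x
  for (j in seq_len(n - 1)) {
    c_j <- A[j + 1] * kap_face_int[j] / dxc[j]
    diagm[j] <- diagm[j] + c_j
    diagm[j + 1] <- diagm[j + 1] + c_j
    upper[j] <- upper[j] - c_j
    lower[j] <- lower[j] - c_j
    rhs[j] <- rhs[j] - A[j + 1] * kap_face_int[j] * rho_f * gx
    rhs[j + 1] <- rhs[j + 1] + A[j + 1] * kap_face_int[j] * rho_f * gx
  }
  have_dirichlet <- FALSE
  p_out <- config$bc$pressure$outer
  if (!is.na(p_out)) {
    have_dirichlet <- TRUE
    dxh <- g$edges[n + 1] - g$centers[n]
    c_b <- A[n + 1] * kap[n] / dxh
    diagm[n] <- diagm[n] + c_b
    rhs[n] <- rhs[n] + c_b * p_out - A[n + 1] * kap[n] * rho_f * gx
  }
  p_in <- config$bc$pressure$inner
  if (!is.na(p_in) && A[1] > 0) {
    have_dirichlet <- TRUE
    dxh <- g$centers[1] - g$edges[1]
    c_b <- A[1] * kap[1] / dxh
    diagm[1] <- diagm[1] + c_b
    rhs[1] <- rhs[1] + c_b * p_in + A[1] * kap[1] * rho_f * gx
  }
  if (!have_dirichlet) {
    gc <- config$bc$gauge_cell
    if (is.null(gc))
      stop("all-Neumann pressure problem: set bc$gauge_cell to pin the gauge")
    diagm[gc] <- diagm[gc] + 1
  }
  p <- thomas_solve(lower, diagm, upper, rhs)
  ## face fluxes eps_f v_f (positive along +x)
  face_flux <- numeric(n + 1)
  for (j in seq_len(n - 1))
    face_flux[j + 1] <- -kap_face_int[j] *
      ((p[j + 1] - p[j]) / dxc[j] - rho_f * gx)
  if (!is.na(p_out)) {
    dxh <- g$edges[n + 1] - g$centers[n]
    face_flux[n + 1] <- -kap[n] * ((p_out - p[n]) / dxh - rho_f * gx)
  }
  if (!is.na(p_in) && A[1] > 0) {
    dxh <- g$centers[1] - g$edges[1]
    face_flux[1] <- -kap[1] * ((p[1] - p_in) / dxh - rho_f * gx)
  }
  eps_face <- c(eps_f[1], (eps_f[-n] + eps_f[-1]) / 2, eps_f[n])
  list(p = p, face_flux = face_flux, v_face = face_flux / eps_face)
}

thomas_solve <- function(lower, diagm, upper, rhs) {
  n <- length(diagm)
  if (n == 1) return(rhs / diagm)
  cp <- numeric(n - 1); dp <- numeric(n)
  cp[1] <- upper[1] / diagm[1]
  dp[1] <- rhs[1] / diagm[1]
  for (i in 2:n) {
    m <- diagm[i] - lower[i - 1] * (if (i > 1) cp[i - 1] else 0)
    if (i < n) cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

## Ghost fluid composition at the outer boundary under per-species
## Dirichlet values; the reference species absorbs the renormalization.
ghost_composition <- function(omega_cell, bc_species, ref) {
  om <- omega_cell
  for (sp in names(bc_species)) {
    b <- bc_species[[sp]]
    if (identical(b$type, "dirichlet")) om[[sp]] <- b$value
  }
  om[[ref]] <- om[[ref]] + (1 - sum(om))
  om
}

## ---- right-hand side -------------------------------------------------

#' Assemble the semi-discrete right-hand side of the two-phase model
#'
#' Prognostic fields: solid volume fraction `eps_s` and the non-reference
#' mass fractions of both phases (reference species by the sum constraint,
#' fluid fraction by `eps_f = 1 - eps_s`).  Sequence per evaluation:
#' kinetics and transfer from the current potentials, elliptic pressure
#' solve, Darcy velocity, upwind advection + two-point-flux diffusion.
#'
#' @param state either a packed numeric state vector or the list returned
#'   by the internal unpacker.
#' @param config a [scenario_2p()].
#' @param diagnostics if `TRUE`, attach fluxes, rates, pressure and
#'   entropy-relevant quantities to the result.
#' @return list with `dy` (packed derivative) and, when requested, `extras`.
#' @export
assemble_rhs <- function(state, config, diagnostics = FALSE) {
  if (is.numeric(state)) state <- unpack_state_2p(config, state)
  g <- config$grid; n <- g$n
  fph <- config$phases$f; sph <- config$phases$s
  eps_s <- state$eps_s; eps_f <- state$eps_f
  if (any(eps_s < -1e-6 | eps_s > 1 + 1e-6))
    stop("eps_s outside [0,1] in cell(s) ",
         paste(which(eps_s < -1e-6 | eps_s > 1 + 1e-6), collapse = ", "))
  rho_f <- config$densities[["f"]]; rho_s <- config$densities[["s"]]
  thermo <- config$thermo; species <- config$species
  omega_f <- state$omega_f; omega_s <- state$omega_s

  mu_f <- potentials_matrix(omega_f, "f", thermo, species)
  mu_s <- potentials_matrix(omega_s, "s", thermo, species)

  M <- transfer_matrix_2p(config, mu_f, mu_s)     # fluid -> solid
  Tnet <- rowSums(M)
  rx <- reaction_matrix_2p(config, mu_s, omega_s)

  ps <- solve_pressure(state, config,
                       source_vol = Tnet * (1 / rho_s - 1 / rho_f))

  ## --- fluid fluxes at faces (species mass flux, +x oriented) ----------
  dxc <- diff(g$centers)
  rt <- thermo$gas_constant * thermo$temperature
  dvec_f <- config$coeffs$diffusivity$f
  mwv <- species$molar_mass
  flux_f <- matrix(0, n + 1, length(fph$members),
                   dimnames = list(NULL, fph$members))
  nonref_f <- members_nonref(fph)
  ## mobility factor per cell: eps rho d omega MW / (R theta)
  diff_entropy <- 0
  if (n > 1) {
    for (sp in nonref_f) {
      d_i <- if (!is.null(dvec_f) && sp %in% names(dvec_f)) dvec_f[[sp]] else 0
      if (d_i > 0) {
        mob <- eps_f * rho_f * d_i * pmax(omega_f[, sp], 0) * mwv[[sp]] / rt
        mob_face <- (mob[-n] + mob[-1]) / 2
        dmu <- (mu_f[, sp] - mu_f[, fph$reference_species])
        grad <- diff(dmu) / dxc
        flux_f[2:n, sp] <- -mob_face * grad
        diff_entropy <- diff_entropy +
          sum(mob_face * grad^2 * g$face_areas[2:n] * dxc) / thermo$temperature
      }
    }
  }
  ## outer-boundary diffusive flux for Dirichlet species
  bc_sp <- config$bc$species
  om_ghost <- NULL
  if (length(bc_sp)) {
    om_ghost <- ghost_composition(omega_f[n, ], bc_sp, fph$reference_species)
    mu_ghost <- phase_potentials(pmax(om_ghost, 0) / sum(pmax(om_ghost, 0)),
                                 "f", thermo, species, tol = Inf)
    dxh <- g$edges[n + 1] - g$centers[n]
    for (sp in names(bc_sp)) {
      if (!identical(bc_sp[[sp]]$type, "dirichlet")) next
      d_i <- if (!is.null(dvec_f) && sp %in% names(dvec_f)) dvec_f[[sp]] else 0
      if (d_i > 0) {
        mob <- eps_f[n] * rho_f * d_i * pmax(omega_f[n, sp], 0) *
          mwv[[sp]] / rt
        grad <- ((mu_ghost[[sp]] - mu_ghost[[fph$reference_species]]) -
                   (mu_f[n, sp] - mu_f[n, fph$reference_species])) / dxh
        flux_f[n + 1, sp] <- -mob * grad
        diff_entropy <- diff_entropy +
          mob * grad^2 * g$face_areas[n + 1] * dxh / thermo$temperature
      }
    }
  }
  ## reference species completes each face so that sum_i omega_i u_i = 0
  flux_f[, fph$reference_species] <-
    -rowSums(flux_f[, nonref_f, drop = FALSE])

  ## advective fluxes: upwinded omega times rho_f * (eps_f v_f)
  q <- ps$face_flux                     # eps_f v_f at faces
  adv_f <- matrix(0, n + 1, length(fph$members),
                  dimnames = list(NULL, fph$members))
  if (n > 1) {
    for (j in 2:n) {
      up <- if (q[j] >= 0) j - 1 else j
      adv_f[j, ] <- rho_f * q[j] * omega_f[up, ]
    }
  }
  ## outer face: outflow carries the boundary cell, inflow the ghost state
  if (q[n + 1] >= 0) {
    adv_f[n + 1, ] <- rho_f * q[n + 1] * omega_f[n, ]
  } else {
    om_in <- if (!is.null(om_ghost)) om_ghost else omega_f[n, ]
    adv_f[n + 1, ] <- rho_f * q[n + 1] * om_in
  }
  if (g$face_areas[1] > 0 && !is.na(config$bc$pressure$inner)) {
    adv_f[1, ] <- rho_f * q[1] * omega_f[1, ]   # outflow orientation -x
  }

  ## --- solid diffusion ------------------------------------------------
  dvec_s <- config$coeffs$diffusivity$s
  flux_s <- matrix(0, n + 1, length(sph$members),
                   dimnames = list(NULL, sph$members))
  nonref_s <- members_nonref(sph)
  if (n > 1 && !is.null(dvec_s)) {
    for (sp in nonref_s) {
      d_i <- if (sp %in% names(dvec_s)) dvec_s[[sp]] else 0
      if (d_i > 0) {
        mob <- eps_s * rho_s * d_i * pmax(omega_s[, sp], 0) * mwv[[sp]] / rt
        mob_face <- (mob[-n] + mob[-1]) / 2
        dmu <- (mu_s[, sp] - mu_s[, sph$reference_species])
        grad <- diff(dmu) / dxc
        flux_s[2:n, sp] <- -mob_face * grad
        diff_entropy <- diff_entropy +
          sum(mob_face * grad^2 * g$face_areas[2:n] * dxc) / thermo$temperature
      }
    }
    flux_s[, sph$reference_species] <-
      -rowSums(flux_s[, nonref_s, drop = FALSE])
  }

  ## --- divergences and mass tendencies --------------------------------
  A <- g$face_areas; V <- g$volumes
  divg <- function(flux_mat)
    (A[-1] * flux_mat[-1, , drop = FALSE] -
       A[-(n + 1)] * flux_mat[-(n + 1), , drop = FALSE]) / V

  dm_f <- -divg(adv_f + flux_f)
  for (sp in colnames(M)) {
    if (sp %in% fph$members) dm_f[, sp] <- dm_f[, sp] - M[, sp]
  }
  dm_s <- -divg(flux_s) + eps_s * rx$r
  for (sp in colnames(M)) {
    if (sp %in% sph$members) dm_s[, sp] <- dm_s[, sp] + M[, sp]
  }

  deps_s <- rowSums(dm_s) / rho_s
  deps_f <- -deps_s
  ## consistency: the pressure solve makes the summed fluid equation give
  ## d(eps_f rho_f)/dt = rowSums(dm_f) = rho_f * deps_f up to solver
  ## residual; omega tendencies remove the phase-mass part exactly.
  dom_s <- (dm_s - outer(deps_s * rho_s, rep(1, ncol(dm_s))) * omega_s) /
    (pmax(eps_s, 1e-12) * rho_s)
  dom_f <- (dm_f - outer(deps_f * rho_f, rep(1, ncol(dm_f))) * omega_f) /
    (pmax(eps_f, 1e-12) * rho_f)

  dy <- pack_state_2p(config, deps_s,
                      dom_f[, fph$members, drop = FALSE],
                      dom_s[, sph$members, drop = FALSE])
  if (!diagnostics) return(list(dy = dy))
  list(dy = dy,
       extras = list(pressure = ps$p, face_flux = ps$face_flux,
                     v_face = ps$v_face, transfer = M,
                     reaction = rx$r, affinity = rx$affinity,
                     keff = rx$keff, flux_f = flux_f, adv_f = adv_f,
                     flux_s = flux_s, mu_f = mu_f, mu_s = mu_s,
                     diffusion_entropy = diff_entropy,
                     dm_f = dm_f, dm_s = dm_s))
}

#' Integrate the closed two-phase model
#'
#' Method-of-lines integration with an implicit stiff integrator
#' (`deSolve`), sequential per evaluation: pressure solve, Darcy velocity,
#' transport + kinetics.  Diagnostics (species masses, entropy ledger,
#' global balance residuals) are recorded at every output time.
#'
#' @param config a [scenario_2p()].
#' @param times output times (s), starting at 0.
#' @param diagnostics record mass balances and the entropy ledger at every
#'   output time (default); `FALSE` skips them (faster, e.g. inside
#'   parameter-recovery loops).
#' @return object of class `sim_result_2p`: list with `times`, `fields`
#'   (list of arrays over time), `diagnostics`, `config`.
#' @export
simulate2p <- function(config, times, diagnostics = TRUE) {
  y0 <- pack_state_2p(config, config$initial$eps_s,
                      config$initial$omega_f, config$initial$omega_s)
  rhs_fun <- function(t, y, parms) list(assemble_rhs(y, config)$dy)
  sol <- deSolve::ode(y = y0, times = times, func = rhs_fun, parms = NULL,
                      method = config$solver$method,
                      rtol = config$solver$rtol, atol = config$solver$atol)
  if (attr(sol, "istate")[1] < 0)
    stop("time integration failed (step-size collapse); last time reached: ",
         max(sol[, 1]))
  nt <- nrow(sol)
  n <- config$grid$n
  fph <- config$phases$f; sph <- config$phases$s
  eps_s_t <- matrix(NA_real_, nt, n)
  omega_f_t <- array(NA_real_, c(nt, n, length(fph$members)),
                     dimnames = list(NULL, NULL, fph$members))
  omega_s_t <- array(NA_real_, c(nt, n, length(sph$members)),
                     dimnames = list(NULL, NULL, sph$members))
  p_t <- matrix(NA_real_, nt, n)
  diag_rows <- vector("list", nt)
  V <- config$grid$volumes
  for (it in seq_len(nt)) {
    st <- unpack_state_2p(config, sol[it, -1])
    eps_s_t[it, ] <- st$eps_s
    omega_f_t[it, , ] <- st$omega_f[, fph$members]
    omega_s_t[it, , ] <- st$omega_s[, sph$members]
    if (!diagnostics) next
    ex <- assemble_rhs(sol[it, -1], config, diagnostics = TRUE)$extras
    p_t[it, ] <- ex$pressure
    mass_f <- colSums(V * st$eps_f * config$densities[["f"]] * st$omega_f)
    mass_s <- colSums(V * st$eps_s * config$densities[["s"]] * st$omega_s)
    ledger <- ledger_from_extras_2p(config, st, ex)
    diag_rows[[it]] <- list(
      mass_f = mass_f, mass_s = mass_s,
      transfer_total = colSums(V * ex$transfer),
      reaction_total = colSums(V * st$eps_s * ex$reaction),
      boundary_influx = -config$grid$face_areas[n + 1] *
        (ex$adv_f[n + 1, ] + ex$flux_f[n + 1, ]),
      ledger = ledger)
  }
  structure(list(times = sol[, 1], eps_s = eps_s_t, omega_f = omega_f_t,
                 omega_s = omega_s_t, pressure = p_t,
                 diagnostics = diag_rows, config = config,
                 seed = config$seed),
            class = "sim_result_2p")
}

## Domain-integrated entropy ledger for one two-phase snapshot.
ledger_from_extras_2p <- function(config, st, ex) {
  th <- config$thermo$temperature
  V <- config$grid$volumes
  n <- config$grid$n
  reaction <- sum(V * st$eps_s * ex$keff * ex$affinity^2) / th
  psi <- config$body_potential
  transfer <- 0
  for (tr in config$transfers) {
    sp <- tr$species
    delta <- (ex$mu_f[, sp] + psi[["f"]]) - (ex$mu_s[, sp] + psi[["s"]])
    transfer <- transfer + sum(V * tr$transfer_coeff * delta^2) / th
  }
  r_hat <- config$coeffs$resistance$f
  eps_face <- c(st$eps_f[1], (st$eps_f[-n] + st$eps_f[-1]) / 2, st$eps_f[n])
  vloc <- ex$face_flux / eps_face
  gg <- config$grid
  dx_face <- c(gg$centers[1] - gg$edges[1], diff(gg$centers),
               gg$edges[n + 1] - gg$centers[n])
  Vface <- gg$face_areas * dx_face
  momentum_fluid <- sum(r_hat * vloc^2 * Vface) / th
  entropy_ledger(c(stress_fluid = 0, stress_solid = 0, stress_interface = 0,
                   diffusion = as.numeric(ex$diffusion_entropy),
                   reaction = reaction, transfer = transfer,
                   momentum_fluid = momentum_fluid,
                   momentum_interface = 0, porosity = 0))
}

#' @export
print.sim_result_2p <- function(x, ...) {
  cat(sprintf("<sim_result_2p> %d output times over [%g, %g] s, %d cells\n",
              length(x$times), min(x$times), max(x$times), x$config$grid$n))
  invisible(x)
}

#' Per-species conservation report
#'
#' For every species and phase, compares the storage change between the
#' first and last output time against the time-integrated (trapezoidal)
#' reaction, transfer and boundary-flux terms recorded in the diagnostics.
#'
#' @param result a `sim_result_2p` from [simulate2p()].
#' @return data frame with columns `phase`, `species`, `storage_change`,
#'   `integrated_sources`, `residual`, `relative_residual`.
#' @export
conservation_report <- function(result) {
  tt <- result$times
  nt <- length(tt)
  trapz <- function(f) sum(diff(tt) * (f[-1] + f[-nt]) / 2)
  fph <- result$config$phases$f; sph <- result$config$phases$s
  rows <- list()
  get_series <- function(field, sp)
    vapply(result$diagnostics, function(d) {
      v <- d[[field]]
      if (sp %in% names(v)) v[[sp]] else 0
    }, numeric(1))
  for (sp in fph$members) {
    m <- vapply(result$diagnostics, function(d) d$mass_f[[sp]], numeric(1))
    src <- trapz(get_series("boundary_influx", sp)) -
      trapz(get_series("transfer_total", sp))
    rows[[length(rows) + 1]] <- data.frame(
      phase = "f", species = sp, storage_change = m[nt] - m[1],
      integrated_sources = src)
  }
  for (sp in sph$members) {
    m <- vapply(result$diagnostics, function(d) d$mass_s[[sp]], numeric(1))
    src <- trapz(get_series("reaction_total", sp)) +
      trapz(get_series("transfer_total", sp))
    rows[[length(rows) + 1]] <- data.frame(
      phase = "s", species = sp, storage_change = m[nt] - m[1],
      integrated_sources = src)
  }
  out <- do.call(rbind, rows)
  out$residual <- out$storage_change - out$integrated_sources
  scale <- pmax(abs(out$storage_change), abs(out$integrated_sources), 1e-300)
  out$relative_residual <- out$residual / scale
  out
}

#' Total species mass trajectories
#'
#' @param result a `sim_result_2p`.
#' @param species species symbol.
#' @param phase `"f"`, `"s"` or `"total"`.
#' @return numeric vector over output times (kg).
#' @export
species_mass <- function(result, species, phase = "total") {
  f <- vapply(result$diagnostics, function(d)
    if (species %in% names(d$mass_f)) d$mass_f[[species]] else 0, numeric(1))
  s <- vapply(result$diagnostics, function(d)
    if (species %in% names(d$mass_s)) d$mass_s[[species]] else 0, numeric(1))
  switch(phase, f = f, s = s, total = f + s)
}
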