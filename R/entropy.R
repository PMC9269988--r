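## Numeric evaluation of the flux-force term groups of the restricted
## simplified entropy inequalities, as closure-substituted quadratic forms.

#' Entropy-production ledger
#'
#' Named per-term-group entropy production densities with their total.  With
#' closure-consistent inputs (all coefficients nonnegative, PSD tensors)
#' every group is a nonnegative quadratic form divided by the temperature;
#' groups eliminated by zero-order closures (stresses) are reported as
#' structural zeros to keep the ledger aligned with the inequality's line
#' structure.
#'
#' @param groups named numeric vector of per-group production densities.
#' @return object of class `entropy_ledger` (named numeric with a `total`
#'   attribute).
#' @export
entropy_ledger <- function(groups) {
  structure(groups, total = sum(groups), class = "entropy_ledger")
}

#' @export
print.entropy_ledger <- function(x, ...) {
  cat("<entropy_ledger> total =", format(attr(x, "total"), digits = 6), "\n")
  v <- as.numeric(x)
  names(v) <- names(x)
  print(v)
  invisible(x)
}

#' Total entropy production of a ledger
#' @param ledger an [entropy_ledger()].
#' @return scalar total production.
#' @export
ledger_total <- function(ledger) attr(ledger, "total")

## Quadratic form v' R v with flexible tensor input.
qform <- function(v, R) {
  v <- if (length(v) == 1) c(v, 0, 0) else as.numeric(v)
  R <- as_tensor(R, "resistance")
  as.numeric(t(v) %*% R %*% v)
}

#' Audit a two-phase state against the restricted entropy inequality
#'
#' Evaluates every term group as its closure-substituted quadratic form
#' divided by the temperature: chemical-potential diffusion, affinity
#' reactions, interphase transfer, fluid and interface momentum resistance,
#' and the porosity (normal-force) closure.  Stress groups are structurally
#' zero under the zero-order stress closures.
#'
#' @param state list with per-phase entries `eps`, `rho`, `omega` (named
#'   list with `f`, `s` elements where relevant) and `body_potential`
#'   (named numeric).
#' @param coeffs a [closure_coeffs()]; `resistance$f` (and optional
#'   `resistance$fs`) feed the momentum groups.
#' @param thermo a [thermo_params()].
#' @param species a [species_table()].
#' @param phases named list of [phase_def()] (`f`, `s`).
#' @param reactions list of [reaction_spec()].
#' @param transfers list of [transfer_spec()].
#' @param grad_mu optional named list per phase of matrices (3 columns) or
#'   named vectors of 1-D chemical-potential gradients (J/(kg m)).
#' @param v_f,v_s,v_fs phase/interface velocities (length 3 or scalar).
#' @param porosity_bracket normal-force bracket for the porosity closure
#'   (Pa).
#' @param check_signs if `TRUE`, negative raw coefficients are allowed
#'   through so that sign violations show up in the ledger (audit probe);
#'   default evaluates the closure forms as signed quadratic forms either
#'   way.
#' @return an [entropy_ledger()].
#' @export
audit_two_phase <- function(state, coeffs, thermo, species, phases,
                            reactions = list(), transfers = list(),
                            grad_mu = NULL, v_f = 0, v_s = 0, v_fs = NULL,
                            porosity_bracket = 0, check_signs = FALSE) {
  if (thermo$temperature <= 0) stop("temperature must be positive")
  th <- thermo$temperature
  ## potentials per phase
  mu <- list()
  for (ph in names(phases))
    mu[[ph]] <- phase_potentials(state$omega[[ph]], ph, thermo, species,
                                 tol = 1e-8)
  ## diffusion: sum_phase sum_i eps rho D_i |grad(mu_i - mu_N)|^2 / theta
  diffusion <- 0
  if (!is.null(grad_mu)) {
    for (ph in names(phases)) {
      gm <- grad_mu[[ph]]
      if (is.null(gm)) next
      pd <- phases[[ph]]
      ref <- pd$reference_species
      gref <- grad_of(gm, ref)
      dvec <- coeffs$diffusivity[[ph]]
      for (sp in members_nonref(pd)) {
        d_i <- if (!is.null(dvec) && sp %in% names(dvec)) dvec[[sp]] else 0
        if (d_i == 0) next
        D <- mobility(d_i, state$omega[[ph]][[sp]],
                      species$molar_mass[[sp]], thermo)
        gd <- grad_of(gm, sp) - gref
        diffusion <- diffusion +
          state$eps[[ph]] * state$rho[[ph]] * D * sum(gd^2) / th
      }
    }
  }
  ## reactions: eps K A^2 / theta
  reaction <- 0
  for (rx in reactions) {
    A <- affinity(rx, mu[[rx$phase]], species)
    k <- effective_rate_coeff_signed(rx, state$omega[[rx$phase]], check_signs)
    reaction <- reaction + state$eps[[rx$phase]] * k * A^2 / th
  }
  ## transfer: K_M delta^2 / theta
  psi <- state$body_potential
  if (is.null(psi)) psi <- c(f = 0, s = 0)
  transfer <- 0
  for (tr in transfers) {
    delta <- (mu[[tr$donor]][[tr$species]] + psi[[tr$donor]]) -
      (mu[[tr$receiver]][[tr$species]] + psi[[tr$receiver]])
    transfer <- transfer + tr$transfer_coeff * delta^2 / th
  }
  ## momentum
  momentum_fluid <- if (!is.null(coeffs$resistance$f))
    qform(vdiff(v_f, v_s), coeffs$resistance$f) / th else 0
  momentum_interface <- if (!is.null(coeffs$resistance$fs) && !is.null(v_fs))
    qform(vdiff(v_fs, v_s), coeffs$resistance$fs) / th else 0
  porosity <- coeffs$compressibility * porosity_bracket^2 / th
  entropy_ledger(c(
    stress_fluid = 0, stress_solid = 0, stress_interface = 0,
    diffusion = diffusion, reaction = reaction, transfer = transfer,
    momentum_fluid = momentum_fluid,
    momentum_interface = momentum_interface, porosity = porosity))
}

grad_of <- function(gm, sp) {
  if (is.matrix(gm)) {
    if (sp %in% rownames(gm)) gm[sp, ] else rep(0, ncol(gm))
  } else {
    if (sp %in% names(gm)) gm[[sp]] else 0
  }
}

vdiff <- function(a, b) {
  v3 <- function(x) if (length(x) == 1) c(x, 0, 0) else as.numeric(x)
  v3(a) - v3(b)
}

effective_rate_coeff_signed <- function(rx, omega, allow_negative) {
  if (allow_negative) {
    k <- rx$rate_coeff
    if (!is.null(rx$modulation)) k <- k * rx$modulation(omega)
    k
  } else effective_rate_coeff(rx, omega)
}

#' Audit a three-phase state against the restricted entropy inequality
#'
#' As [audit_two_phase()] with the additional three-phase groups: transfer
#' over the three phase pairs, per-fluid momentum resistance (with optional
#' viscous cross-coupling), capillary-pressure relaxation, and the
#' porosity work split over the wetted and non-wetted solid surface.  The
#' porosity lines certify only their sum; the ledger apportions the
#' nonnegative total by wetted fraction so each reported group is a
#' nonnegative quadratic form.
#'
#' @param state as in [audit_two_phase()], with phases `w`, `n`, `s`.
#' @param geometry a [geometry_state()] (supplies curvature and wetted
#'   fraction).
#' @param coeffs a [closure_coeffs()].
#' @param thermo a [thermo_params()].
#' @param species a [species_table()].
#' @param phases named list of [phase_def()] (`w`, `n`, `s`).
#' @param reactions,transfers kinetic specifications.
#' @param grad_mu optional per-phase potential gradients.
#' @param v_w,v_n,v_s phase velocities.
#' @param p_w,p_n interface fluid pressures (Pa) for the capillary group.
#' @param porosity_bracket three-phase normal-force bracket (Pa), e.g. from
#'   [porosity_bracket()].
#' @param check_signs see [audit_two_phase()].
#' @return an [entropy_ledger()].
#' @export
audit_three_phase <- function(state, geometry, coeffs, thermo, species,
                              phases, reactions = list(), transfers = list(),
                              grad_mu = NULL, v_w = 0, v_n = 0, v_s = 0,
                              p_w = 0, p_n = 0, porosity_bracket = 0,
                              check_signs = FALSE) {
  if (thermo$temperature <= 0) stop("temperature must be positive")
  th <- thermo$temperature
  mu <- list()
  for (ph in names(phases))
    mu[[ph]] <- phase_potentials(state$omega[[ph]], ph, thermo, species,
                                 tol = 1e-8)
  diffusion <- 0
  if (!is.null(grad_mu)) {
    for (ph in names(phases)) {
      gm <- grad_mu[[ph]]
      if (is.null(gm)) next
      pd <- phases[[ph]]
      gref <- grad_of(gm, pd$reference_species)
      dvec <- coeffs$diffusivity[[ph]]
      for (sp in members_nonref(pd)) {
        d_i <- if (!is.null(dvec) && sp %in% names(dvec)) dvec[[sp]] else 0
        if (d_i == 0) next
        D <- mobility(d_i, state$omega[[ph]][[sp]],
                      species$molar_mass[[sp]], thermo)
        gd <- grad_of(gm, sp) - gref
        diffusion <- diffusion +
          state$eps[[ph]] * state$rho[[ph]] * D * sum(gd^2) / th
      }
    }
  }
  reaction <- 0
  for (rx in reactions) {
    A <- affinity(rx, mu[[rx$phase]], species)
    k <- effective_rate_coeff_signed(rx, state$omega[[rx$phase]], check_signs)
    reaction <- reaction + state$eps[[rx$phase]] * k * A^2 / th
  }
  psi <- state$body_potential
  if (is.null(psi)) psi <- c(w = 0, n = 0, s = 0)
  pair_of <- function(a, b) paste0(sort(c(a, b)), collapse = "")
  transfer_groups <- c(wn = 0, ws = 0, ns = 0)
  for (tr in transfers) {
    delta <- (mu[[tr$donor]][[tr$species]] + psi[[tr$donor]]) -
      (mu[[tr$receiver]][[tr$species]] + psi[[tr$receiver]])
    key <- pair_of(tr$donor, tr$receiver)
    key <- c(nw = "wn", sw = "ws", ns = "ns", wn = "wn", ws = "ws")[[key]]
    transfer_groups[[key]] <- transfer_groups[[key]] +
      tr$transfer_coeff * delta^2 / th
  }
  ## momentum: block form sum_{a,k} (v_a - v_s) R^{ka} (v_k - v_s);
  ## the per-phase groups carry their own diagonal + cross terms
  dv <- list(w = vdiff(v_w, v_s), n = vdiff(v_n, v_s))
  Rw <- coeffs$resistance$w; Rn <- coeffs$resistance$n
  Rwn <- coeffs$resistance$cross
  momentum_w <- if (!is.null(Rw)) qform(dv$w, Rw) / th else 0
  momentum_n <- if (!is.null(Rn)) qform(dv$n, Rn) / th else 0
  if (!is.null(Rwn)) {
    crossterm <- as.numeric(t(dv$w) %*% as_tensor(Rwn, "cross") %*% dv$n) / th
    momentum_w <- momentum_w + crossterm
    momentum_n <- momentum_n + crossterm
  }
  ## capillary relaxation: c_wn (p_w - p_n - gamma J)^2 / theta
  gamma_wn <- if ("wn" %in% names(coeffs$tension)) coeffs$tension[["wn"]] else 0
  deviation <- p_w - p_n - gamma_wn * geometry$J_w_wn
  capillary <- coeffs$capillary_relaxation * deviation^2 / th
  ## porosity work, apportioned by wetted fraction (sum = c_ss bracket^2/th)
  porosity_total <- coeffs$compressibility * porosity_bracket^2 / th
  chi <- geometry$chi_s_ws
  entropy_ledger(c(
    stress_fluid = 0, stress_solid = 0, stress_interface = 0,
    diffusion = diffusion, reaction = reaction,
    transfer_wn = transfer_groups[["wn"]],
    transfer_ws = transfer_groups[["ws"]],
    transfer_ns = transfer_groups[["ns"]],
    momentum_w = momentum_w, momentum_n = momentum_n,
    capillary_relaxation = capillary,
    porosity_ws = chi * porosity_total,
    porosity_ns = (1 - chi) * porosity_total))
}

#' Seeded random thermodynamic states for audit property checks
#'
#' Draws a random, fully valid non-equilibrium state (compositions,
#' coefficients, gradients, velocities, brackets) for the two- or
#' three-phase audit.  All coefficients are nonnegative by construction, so
#' every ledger group must come out nonnegative.
#'
#' @param seed integer seed.
#' @param model `"2p"` or `"3p"`.
#' @return list with the arguments needed by the corresponding audit
#'   function.
#' @export
random_thermo_state <- function(seed, model = c("2p", "3p")) {
  model <- match.arg(model)
  set.seed(seed)
  species <- default_species_table(model)
  phases <- default_phase_defs(model)
  runit <- function(n) stats::runif(n)
  omega <- lapply(phases, function(pd) {
    w <- stats::rexp(length(pd$members)) + 1e-6
    stats::setNames(w / sum(w), pd$members)
  })
  nph <- length(phases)
  eps_raw <- stats::rexp(nph) + 0.05
  eps <- stats::setNames(eps_raw / sum(eps_raw), names(phases))
  rho <- stats::setNames(800 + 400 * runit(nph), names(phases))
  thermo <- thermo_params(temperature = 300 + 20 * runit(1),
                          mu0 = default_mu0(names(phases)))
  grad_mu <- lapply(phases, function(pd) {
    g <- matrix(stats::rnorm(3 * length(pd$members), sd = 1e3), ncol = 3,
                dimnames = list(pd$members, NULL))
    g
  })
  diffusivity <- lapply(phases, function(pd)
    stats::setNames(stats::runif(length(pd$members), 0, 2e-9), pd$members))
  reactions <- if (model == "2p") {
    tumor_reactions(species, "s",
                    k_growth = stats::runif(1, 0, 2e-7),
                    k_destruction = stats::runif(1, 0, 1e-7),
                    k_necrosis = stats::runif(1, 0, 2e-7),
                    k_lysis = stats::runif(1, 0, 1e-7))
  } else {
    ## non-wetting phase lacks the matrix species; debris species x stands
    ## in for the destruction/lysis products (see the 3P fixture)
    list(
      reaction_spec("growth", "n",
                    balance_stoichiometry(c(g = -1, o = -6, l = NA), "l",
                                          species),
                    stats::runif(1, 0, 2e-7)),
      reaction_spec("necrosis", "n", c(l = -1, n = 1),
                    stats::runif(1, 0, 2e-7),
                    modulation = oxygen_switch()),
      reaction_spec("lysis", "n",
                    balance_stoichiometry(c(n = -1, x = 1, w = NA), "w",
                                          species),
                    stats::runif(1, 0, 1e-7)))
  }
  shared_pairs <- if (model == "2p") {
    list(c("f", "s"))
  } else {
    list(c("w", "n"), c("w", "s"), c("n", "s"))
  }
  transfers <- list()
  for (pr in shared_pairs) {
    shared <- intersect(phases[[pr[1]]]$members, phases[[pr[2]]]$members)
    for (sp in shared)
      transfers[[length(transfers) + 1]] <-
        transfer_spec(sp, pr[1], pr[2], stats::runif(1, 0, 1e-6))
  }
  state <- list(eps = as.list(eps), rho = as.list(rho), omega = omega,
                body_potential = stats::setNames(stats::rnorm(nph, sd = 10),
                                                 names(phases)))
  coeffs <- closure_coeffs(
    diffusivity = diffusivity,
    resistance = if (model == "2p") list(f = stats::runif(1, 1e8, 1e10))
                 else list(w = stats::runif(1, 1e8, 1e10),
                           n = stats::runif(1, 1e8, 1e10)),
    compressibility = stats::runif(1, 0, 1e-8),
    tension = c(fs = stats::runif(1, 0, 0.05), wn = stats::runif(1, 0, 0.05),
                ws = stats::runif(1, 0, 0.05), ns = stats::runif(1, 0, 0.05)),
    capillary_relaxation = stats::runif(1, 0, 1e-6))
  out <- list(state = state, coeffs = coeffs, thermo = thermo,
              species = species, phases = phases, reactions = reactions,
              transfers = transfers, grad_mu = grad_mu,
              porosity_bracket = stats::rnorm(1, sd = 100))
  if (model == "2p") {
    out$v_f <- stats::rnorm(3, sd = 1e-6); out$v_s <- stats::rnorm(3, sd = 1e-7)
  } else {
    out$v_w <- stats::rnorm(3, sd = 1e-6); out$v_n <- stats::rnorm(3, sd = 1e-6)
    out$v_s <- stats::rnorm(3, sd = 1e-7)
    out$geometry <- geometry_state(
      eps = c(w = eps[["w"]], n = eps[["n"]], s = eps[["s"]]),
      areas = c(wn = stats::runif(1, 10, 100), ws = stats::runif(1, 10, 100),
                ns = stats::runif(1, 10, 100)),
      J_w_wn = stats::runif(1, 1e3, 1e4),
      K_n_wn = stats::runif(1, 1e6, 1e8),
      K_n_ns = 0,
      chi_n = stats::runif(1, 1e3, 1e5),
      chi_s_ws = stats::runif(1),
      contact_angle = stats::runif(1, 0, pi / 3))
    out$p_w <- stats::rnorm(1, sd = 100); out$p_n <- stats::rnorm(1, sd = 100)
  }
  out
}
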