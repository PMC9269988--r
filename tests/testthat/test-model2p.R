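test_that("spheroid fixture is deterministic and satisfies state invariants", {
  a <- build_spheroid_fixture(seed = 7, n_cells = 8)
  b <- build_spheroid_fixture(seed = 7, n_cells = 8)
  # identical seeds give identical serialized scenarios
  fa <- tempfile(fileext = ".yaml"); fb <- tempfile(fileext = ".yaml")
  write_config(a, fa); write_config(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(readLines(fa),
                         {write_config(build_spheroid_fixture(seed = 8,
                                                              n_cells = 8),
                                       fb); readLines(fb)}))
  # construction invariants
  expect_equal(a$grid$n, 8)
  expect_true(all(abs(rowSums(a$initial$omega_f) - 1) < 1e-12))
  expect_true(all(abs(rowSums(a$initial$omega_s) - 1) < 1e-12))
  expect_true(all(a$initial$eps_s >= 0 & a$initial$eps_s <= 1))
  # zero bump amplitude gives spatially uniform initial fields
  u <- build_spheroid_fixture(seed = 7, n_cells = 8, bump_amplitude = 0)
  expect_equal(max(apply(u$initial$omega_s, 2, function(col)
    diff(range(col)))), 0)
  expect_error(build_spheroid_fixture(n_cells = 4), "at least 8")
  expect_error(build_spheroid_fixture(nutrient_boundary_values = c(q = 1)),
               "non-fluid")
})

test_that("a constructed equilibrium state is a fixed point of the model", {
  cfg <- build_equilibrium_fixture(4)
  y0 <- initial_packed(cfg)
  expect_lt(max(abs(assemble_rhs(y0, cfg)$dy)), 1e-12)
  res <- simulate2p(cfg, c(0, 500, 5000))
  yT <- tcatsim:::pack_state_2p(cfg, res$eps_s[3, ], res$omega_f[3, , ],
                                res$omega_s[3, , ])
  expect_lt(max(abs(yT - y0)), 1e-10)
})

test_that("the semi-discrete operator matches an independently assembled
           diffusion matrix for an inert solute", {
  cfg <- build_diffusion_fixture(n_cells = 16)
  y0 <- initial_packed(cfg)
  st <- tcatsim:::unpack_state_2p(cfg, y0)
  out <- assemble_rhs(y0, cfg, diagnostics = TRUE)
  n <- 16
  # independent assembly: mass tendency = -div(-mob_face * d(dmu)/dx) with
  # arithmetic face mobilities, matching the two-point-flux stencil
  g <- cfg$grid
  th <- cfg$thermo
  rt <- th$gas_constant * th$temperature
  om <- st$omega_f[, "g"]
  mob <- st$eps_f * 1000 * 1e-9 * om * 0.18 / rt
  mu <- tcatsim:::potentials_matrix(st$omega_f, "f", th, cfg$species)
  dmu <- mu[, "g"] - mu[, "w"]
  dx <- diff(g$centers)
  flux <- c(0, -(mob[-n] + mob[-1]) / 2 * diff(dmu) / dx, 0)
  dm_expected <- -(flux[-1] - flux[-(n + 1)]) / g$volumes
  expect_equal(unname(out$extras$dm_f[, "g"]), dm_expected,
               tolerance = 1e-12)
})

test_that("one-cell transfer dynamics match an independent two-box ODE", {
  cfg <- build_transfer_fixture()
  times <- seq(0, 60, by = 5)
  res <- simulate2p(cfg, times, diagnostics = FALSE)
  # independent oracle: two-compartment ODE in species masses, written
  # directly from the closure definitions (no shared code path)
  st <- cfg$species; th <- cfg$thermo
  K <- cfg$transfers[[1]]$transfer_coeff
  rho <- 1000
  # state: solute mass per volume in each phase; the transferred solute
  # carries its volume (equal densities), shifting eps
  q0 <- c(0.5 * rho * 5e-4, 0.5 * rho * 5e-3)
  rhs <- function(t, q, p) {
    eps_s <- 0.5 + (q[2] - q0[2]) / rho
    eps_f <- 1 - eps_s
    wf <- q[1] / (eps_f * rho); ws <- q[2] / (eps_s * rho)
    mu_f <- tcatsim:::phase_potentials(c(o = wf, w = 1 - wf), "f", th, st,
                                       tol = Inf)
    mu_s <- tcatsim:::phase_potentials(c(o = ws, e = 1 - ws), "s", th, st,
                                       tol = Inf)
    M <- K * (mu_f[["o"]] - mu_s[["o"]])
    list(c(-M, M))
  }
  orac <- deSolve::ode(q0, times, rhs, NULL, rtol = 1e-10, atol = 1e-14)
  eps_s_o <- 0.5 + (orac[, 3] - q0[2]) / rho
  wf_o <- orac[, 2] / ((1 - eps_s_o) * rho)
  ws_o <- orac[, 3] / (eps_s_o * rho)
  expect_equal(res$omega_f[, 1, "o"], unname(wf_o), tolerance = 1e-6)
  expect_equal(res$omega_s[, 1, "o"], unname(ws_o), tolerance = 1e-6)
  # both approach the same augmented potential (transfer equilibrium)
  res <- simulate2p(cfg, c(0, 2000), diagnostics = FALSE)
  wfT <- unname(res$omega_f[2, 1, "o"]); wsT <- unname(res$omega_s[2, 1, "o"])
  mu_f <- tcatsim:::phase_potentials(c(o = wfT, w = 1 - wfT), "f", th, st,
                                     tol = Inf)
  mu_s <- tcatsim:::phase_potentials(c(o = wsT, e = 1 - wsT), "s", th, st,
                                     tol = Inf)
  expect_lt(abs(mu_f[["o"]] - mu_s[["o"]]) /
              abs(mu_f[["o"]]), 1e-4)
})

test_that("the pressure solve reproduces exact Darcy limits", {
  cfg <- build_diffusion_fixture(n_cells = 32)
  cfg$bc$pressure <- list(outer = 50, inner = 200)
  st <- tcatsim:::unpack_state_2p(cfg, initial_packed(cfg))
  ps <- solve_pressure(st, cfg)
  L <- max(cfg$grid$edges)
  exact <- 200 + (50 - 200) * cfg$grid$centers / L
  expect_lt(max(abs(ps$p - exact)), 1e-10 * 200)
  expect_lt(diff(range(ps$face_flux)), 1e-15)
  # uniform Dirichlet: constant pressure, zero velocity
  cfg$bc$pressure <- list(outer = 75, inner = 75)
  ps2 <- solve_pressure(st, cfg)
  expect_equal(ps2$p, rep(75, 32), tolerance = 1e-12)
  expect_lt(max(abs(ps2$v_face)), 1e-14)
  # symmetric point source gives a symmetric field
  cfg$bc$pressure <- list(outer = 0, inner = 0)
  src <- rep(0, 32); src[16] <- 1e-6; src[17] <- 1e-6
  ps3 <- solve_pressure(st, cfg, source_vol = src)
  expect_equal(ps3$p, rev(ps3$p), tolerance = 1e-10)
  # all-Neumann needs a gauge
  cfg$bc$pressure <- list(outer = NA, inner = NA)
  cfg$bc$gauge_cell <- NULL
  expect_error(solve_pressure(st, cfg), "gauge")
})

test_that("closed-domain runs conserve mass and satisfy state closures", {
  cfg <- build_transfer_fixture()
  times <- seq(0, 500, length.out = 11)
  res <- simulate2p(cfg, times)
  m <- species_mass(res, "o", "total")
  expect_lt(max(abs(m - m[1])) / m[1], 1e-8)
  # per-output closures
  expect_true(all(abs(apply(res$omega_f, c(1, 2), sum) - 1) < 1e-10))
  expect_true(all(abs(apply(res$omega_s, c(1, 2), sum) - 1) < 1e-10))
  # transfer antisymmetry: fluid loss equals solid gain
  mf <- species_mass(res, "o", "f"); ms <- species_mass(res, "o", "s")
  expect_lt(abs((mf[1] - mf[11]) - (ms[11] - ms[1])), 1e-8 * m[1])
})

test_that("the conservation report closes storage against sources", {
  # reaction-only run: storage change equals integrated reaction quadrature
  cfg <- build_reaction_fixture()
  res <- simulate2p(cfg, seq(0, 2000, length.out = 41))
  rep_ <- conservation_report(res)
  expect_true(all(abs(rep_$relative_residual) < 1e-3))
  l_row <- rep_[rep_$phase == "s" & rep_$species == "l", ]
  expect_lt(abs(l_row$residual),
            1e-3 * max(abs(l_row$storage_change), 1e-300))
  # closed inert (no kinetics at all): residuals at solver precision
  cfg2 <- build_diffusion_fixture(n_cells = 16)
  res2 <- simulate2p(cfg2, seq(0, 500, length.out = 6))
  rep2 <- conservation_report(res2)
  expect_true(all(abs(rep2$residual) < 1e-10))
})

test_that("entropy ledger stays nonnegative along trajectories", {
  cfg <- build_transfer_fixture()
  res <- simulate2p(cfg, seq(0, 300, length.out = 7))
  expect_gte(min_ledger_group(res), -1e-12)
  tot <- vapply(res$diagnostics, function(d) ledger_total(d$ledger), 1)
  expect_true(all(tot >= 0))
  # transfer entropy decays toward equilibrium
  expect_lt(tot[7], tot[1])
})
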