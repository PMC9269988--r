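test_that("zero-order stress closures are isotropic", {
  expect_equal(phase_stress(0), matrix(0, 3, 3))
  expect_equal(phase_stress(10), diag(c(-10, -10, -10)))
  p <- 3.7
  dev <- phase_stress(p) - diag(3) * sum(diag(phase_stress(p))) / 3
  expect_equal(max(abs(dev)), 0)
})

test_that("interfacial stress is tension times (I - G) with trace 2 gamma", {
  expect_equal(interface_stress(0), matrix(0, 3, 3))
  s <- interface_stress(3, rep(1 / 3, 3))
  expect_equal(s, 2 * diag(3))
  expect_equal(sum(diag(s)), 2 * 3)
  # planar interface limit
  expect_equal(interface_stress(1, c(1, 0, 0)), diag(c(0, 1, 1)))
  expect_error(interface_stress(1, c(1, 1, 0)), "trace 1")
})

test_that("diffusive fluxes close the zero-net-deviation constraint exactly", {
  st <- species_table(c(g = 0.18, o = 0.032, w = 0.018))
  ph <- phase_def("f", c("g", "o", "w"), "w", st)
  th <- thermo_params(310)
  cf <- closure_coeffs(diffusivity = list(f = c(g = 1e-9, o = 2e-9)))
  om <- c(g = 1e-3, o = 1e-4, w = 1 - 1.1e-3)
  # uniform potentials: no flux
  fl0 <- diffusive_flux(ph, 0.5, 1000, om, c(g = 0, o = 0, w = 0), cf, th, st)
  expect_equal(max(abs(fl0)), 0)
  fl <- diffusive_flux(ph, 0.5, 1000, om, c(g = 2e4, o = -1e4, w = 3e3),
                       cf, th, st)
  expect_equal(sum(fl), 0, tolerance = 1e-18)
  # two-species phase: reference flux mirrors the solute exactly
  ph2 <- phase_def("f", c("g", "w"), "w", st)
  fl2 <- diffusive_flux(ph2, 0.5, 1000, c(g = 1e-3, w = 1 - 1e-3),
                        c(g = 5e4), cf, th, st)
  expect_equal(fl2[["w"]], -fl2[["g"]])
  expect_error(
    diffusive_flux(ph2, 0.5, 1000, c(g = 1e-3, w = 1 - 1e-3),
                   c(o = 1), cf, th, st), "non-member")
})

test_that("dilute-limit flux matches the Fickian form on a tabulated profile", {
  # full closure flux vs -rho d grad(omega), central differences
  st <- species_table(c(g = 0.18, w = 0.018))
  ph <- phase_def("f", c("g", "w"), "w", st)
  th <- thermo_params(310)
  d <- 1e-9
  cf <- closure_coeffs(diffusivity = list(f = c(g = d)))
  xs <- seq(0, 1e-3, length.out = 41)
  h <- diff(xs)[1]
  prof <- 1e-4 * exp(-((xs - 5e-4) / 2e-4)^2)
  mu <- vapply(prof, function(w)
    tcatsim:::phase_potentials(c(g = w, w = 1 - w), "f", th, st), numeric(2))
  for (i in c(10, 20, 30)) {
    grad_mu <- c(g = unname(mu["g", i + 1] - mu["g", i - 1]) / (2 * h),
                 w = unname(mu["w", i + 1] - mu["w", i - 1]) / (2 * h))
    fl <- diffusive_flux(ph, 1, 1000, c(g = prof[i], w = 1 - prof[i]),
                         grad_mu, cf, th, st)
    fick <- -1000 * d * (prof[i + 1] - prof[i - 1]) / (2 * h)
    expect_equal(fl[["g"]], fick, tolerance = 5e-3)
  }
})

test_that("quasi-static fluid velocity solves the momentum closure", {
  # closed-form inversion
  expect_equal(fluid_velocity(0.4, 1000, c(5, 0, 0), resistance = 10),
               c(-0.2, 0, 0))
  # equilibrium and hydrostatic balance
  expect_equal(fluid_velocity(0.4, 1000, 0, resistance = 10, v_s = c(1, 0, 0)),
               c(1, 0, 0))
  g <- c(-9.81, 0, 0)
  expect_equal(fluid_velocity(0.4, 1000, 1000 * g, gravity = g,
                              resistance = 10), c(0, 0, 0))
  # transfer momentum: continuity as K_M -> 0
  v0 <- fluid_velocity(0.4, 1000, c(5, 0, 0), resistance = 10)
  vk <- fluid_velocity(0.4, 1000, c(5, 0, 0), resistance = 10,
                       transfer_rates = c(o = 1e-12))
  expect_equal(vk, v0, tolerance = 1e-10)
  # with finite transfer the solution satisfies the balance identically
  M <- c(o = 0.3)
  v <- fluid_velocity(0.4, 1000, c(5, 0, 0), resistance = 10,
                      transfer_rates = M)
  residual <- 0.4 * c(5, 0, 0) + 10 * v + sum(M) * v
  expect_equal(max(abs(residual)), 0, tolerance = 1e-10)
  expect_error(fluid_velocity(0.4, 1000, c(5, 0, 0), resistance = 0),
               "singular")
})

test_that("porosity and capillary closures are linear with clean zeros", {
  expect_equal(porosity_rate(porosity_bracket(100, -90, 10, -1), 0.01), 0)
  expect_equal(porosity_rate(5, 0.01), 0.05)
  expect_equal(porosity_rate(5, 0), 0)
  # three-phase wetted-fraction weighting
  br <- porosity_bracket(c(w = 10, n = 20), -5, c(ws = 0.01, ns = 0.02),
                         100, wetted_fraction = 0.25)
  expect_equal(br, 0.25 * 10 + 0.75 * 20 - 5 +
                 (0.25 * 0.01 + 0.75 * 0.02) * 100)
  # Young-Laplace equilibrium
  expect_equal(capillary_relaxation_rate(120, 100, 0.01, 2000, 0.5), 0)
  expect_equal(capillary_relaxation_rate(102, 100, 0, 0, 0.5), 1)
  expect_equal(capillary_relaxation_rate(98, 100, 0, 0, 0.5), -1)
})

test_that("capillary inversion round-trips through the relaxation closure", {
  set.seed(7)
  for (i in 1:20) {
    gamma <- runif(1, 1e-3, 0.1); J <- runif(1, 1e2, 1e4)
    coeff <- runif(1, 1e-8, 1e-2); rate <- rnorm(1)
    pc <- invert_capillary_pressure(rate, gamma, J, coeff)
    back <- capillary_relaxation_rate(pc, 0, gamma, J, coeff)
    expect_equal(back, rate, tolerance = 1e-12 * max(1, abs(rate)))
  }
})

test_that("closure quadratic forms are nonnegative for seeded random states", {
  set.seed(11)
  for (i in 1:100) {
    grad <- rnorm(3, sd = 1e4)
    D <- runif(1, 0, 1e-9)
    expect_gte(D * sum(grad^2), 0)
    v <- rnorm(3, sd = 1e-5)
    R <- runif(1, 1e8, 1e10)
    expect_gte(R * sum(v^2), 0)
    expect_gte(runif(1, 0, 1e-8) * rnorm(1, sd = 100)^2, 0)  # porosity
    expect_gte(runif(1, 0, 1e-4) * rnorm(1, sd = 10)^2, 0)   # capillary
  }
})
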