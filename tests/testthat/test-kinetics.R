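test_that("stoichiometric mass balance is validated and solvable", {
  st <- lysis_species()
  # isomerization with equal masses balances
  st_iso <- species_table(c(t = 0.1, n = 0.1))
  rx <- reaction_spec("necrosis", "s", c(t = -1, n = 1), 1)
  expect_true(validate_reaction(rx, st_iso)$ok)
  # constructed imbalance reports the residual mass
  st_bad <- species_table(c(t = 0.1, n = 0.09))
  v <- validate_reaction(reaction_spec("bad", "s", c(t = -1, n = 1), 1),
                         st_bad)
  expect_false(v$ok)
  expect_equal(v$residual, -0.01)
  # free coefficient solved from the balance: n -> e + nu_w w
  stoich <- balance_stoichiometry(c(n = -1, e = 1, w = NA), "w", st)
  expect_equal(unname(stoich[["w"]]), 0.04 / 0.018, tolerance = 1e-12)
  expect_true(validate_reaction(reaction_spec("lysis", "s", stoich, 2),
                                st)$ok)
  expect_error(reaction_spec("neg", "s", c(t = -1, n = 1), -1),
               "nonnegative")
})

test_that("affinity is the stoichiometry-weighted potential sum", {
  st <- lysis_species()
  stoich <- balance_stoichiometry(c(n = -1, e = 1, w = NA), "w", st)
  rx <- reaction_spec("lysis", "s", stoich, 2)
  mu <- c(n = -100, e = -200, w = -300)
  A <- affinity(rx, mu, st)
  expect_equal(A, -14, tolerance = 1e-9)
  # equal potentials annihilate a mass-balanced stoichiometry
  expect_equal(affinity(rx, c(n = -7, e = -7, w = -7), st), 0,
               tolerance = 1e-12)
  # invariant under uniform potential shifts
  expect_equal(affinity(rx, mu + 123.4, st), A, tolerance = 1e-9)
  # linear in the coefficients
  rx2 <- reaction_spec("lysis2", "s", 2 * stoich, 2)
  expect_equal(affinity(rx2, mu, st), 2 * A, tolerance = 1e-9)
  expect_error(affinity(rx, c(n = -100, e = -200), st), "missing")
})

test_that("linear affinity closure rates have the dissipative sign", {
  st <- lysis_species()
  stoich <- balance_stoichiometry(c(n = -1, e = 1, w = NA), "w", st)
  rx <- reaction_spec("lysis", "s", stoich, 2)
  expect_equal(reaction_rate(rx, 0), 0)
  expect_equal(reaction_rate(rx, -14), 28)
  rx0 <- reaction_spec("frozen", "s", stoich, 0)
  expect_equal(reaction_rate(rx0, 1e6), 0)
  # entropy production eps K A^2 / theta >= 0 for random affinities
  set.seed(4)
  for (A in rnorm(20, sd = 100))
    expect_gte(-reaction_rate(rx, A) * A, 0)
})

test_that("species production conserves mass reaction by reaction", {
  st <- lysis_species()
  phases <- list(s = phase_def("s", c("n", "e", "w"), "e", st))
  stoich <- balance_stoichiometry(c(n = -1, e = 1, w = NA), "w", st)
  rx <- reaction_spec("lysis", "s", stoich, 2)
  mu <- list(s = c(n = -100, e = -200, w = -300))
  expect_equal(species_production(list(), mu, st), list())
  prod <- species_production(list(rx), mu, st, phase_defs = phases)
  # R = 28: r_n = -1 * 0.1 * 28
  expect_equal(prod$s[["n"]], -2.8, tolerance = 1e-12)
  expect_equal(sum(unlist(prod$s)), 0, tolerance = 1e-14)
  # two half-rate copies reproduce the single reaction
  rx_half <- reaction_spec("lysis_h", "s", stoich, 1)
  prod2 <- species_production(list(rx_half, rx_half), mu, st,
                              phase_defs = phases)
  expect_equal(unlist(prod2$s), unlist(prod$s), tolerance = 1e-12)
  # a reaction referencing a species missing from the phase errors
  phases_missing <- list(s = phase_def("s", c("n", "e"), "e", st))
  expect_error(species_production(list(rx), mu, st,
                                  phase_defs = phases_missing),
               "not in phase")
})

test_that("transfer rates are antisymmetric and vanish at equilibrium", {
  st <- lysis_species()
  phases <- list(f = phase_def("f", "w", "w", st),
                 s = phase_def("s", c("e", "w"), "e", st))
  tr <- transfer_spec("w", "f", "s", 2)
  pots <- list(f = c(w = -50), s = c(w = -80, e = 0))
  expect_equal(transfer_rate(tr, pots, phase_defs = phases), 60)
  tr_rev <- transfer_spec("w", "s", "f", 2)
  expect_equal(transfer_rate(tr_rev, pots, phase_defs = phases), -60)
  # augmented-potential equilibrium (psi absorbs the chemical difference)
  expect_equal(transfer_rate(tr, pots, body_potentials = c(f = 0, s = 30)),
               0)
  expect_error(transfer_rate(transfer_spec("e", "f", "s", 1), pots,
                             phase_defs = phases), "not shared")
})

test_that("modulation factors stay nonnegative and gate rates smoothly", {
  sw <- oxygen_switch(omega_crit = 1e-5, delta = 2e-6)
  expect_lt(sw(c(o = 5e-5)), 1e-8)
  expect_gt(sw(c(o = 1e-6)), 0.9)
  expect_equal(sw(c(o = 1e-5)), 0.5)
  lim <- reactant_limiter("n", scale = 1e-6)
  expect_equal(lim(c(n = 0)), 0)
  expect_gt(lim(c(n = 1e-3)), 0.99)
  both <- compose_modulation(sw, lim)
  expect_equal(both(c(o = 1e-5, n = 1e-6)), 0.5 * lim(c(n = 1e-6)))
  # vectorized over cells
  om <- cbind(o = c(5e-5, 1e-6), n = c(0, 1e-3))
  expect_length(both(om), 2)
  expect_true(all(both(om) >= 0))
})

test_that("reaction + transfer entropy production is nonnegative and mass
           is globally conserved for seeded random states", {
  for (seed in 1:25) {
    rs <- random_thermo_state(seed, "2p")
    mu <- lapply(names(rs$phases), function(ph)
      tcatsim:::phase_potentials(rs$state$omega[[ph]], ph, rs$thermo,
                                 rs$species, tol = 1e-8))
    names(mu) <- names(rs$phases)
    total <- 0
    for (rx in rs$reactions) {
      A <- affinity(rx, mu[[rx$phase]], rs$species)
      R <- reaction_rate(rx, A, rs$state$omega[[rx$phase]])
      expect_gte(-rs$state$eps[[rx$phase]] * R * A, 0)
      # per-reaction species contributions cancel
      mw <- rs$species$molar_mass[names(rx$stoich)]
      expect_equal(sum(rx$stoich * mw * R), 0, tolerance = 1e-12 * abs(R))
    }
    net <- 0
    for (tr in rs$transfers) {
      M <- transfer_rate(tr, mu,
                         body_potentials = unlist(rs$state$body_potential))
      delta <- M / max(tr$transfer_coeff, 1e-300)
      expect_gte(M * delta, 0)    # K delta^2 >= 0
      net <- net + M - M          # donor loss equals receiver gain
    }
    expect_equal(net, 0)
  }
})
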