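test_that("sphere packs realize the analytic geometric densities", {
  g <- sphere_pack_state(1000, 1e-4)
  expect_equal(g$areas[["wn"]], 4 * pi * 1e-8 * 1000)   # ~1.2566e-4
  expect_equal(g$K_n_wn, 1e8)
  expect_equal(g$J_w_wn, 2e4)
  expect_equal(g$eps[["n"]], 4 / 3 * pi * 1e-12 * 1000)
  # empty pack
  g0 <- sphere_pack_state(0, 1e-4)
  expect_equal(g0$eps[["n"]], 0)
  expect_equal(g0$areas[["wn"]], 0)
  expect_equal(g0$K_n_wn, 0)
  # extensivity: doubling N doubles extents, fixes curvatures
  g2 <- sphere_pack_state(2000, 1e-4)
  expect_equal(g2$eps[["n"]], 2 * g$eps[["n"]])
  expect_equal(g2$areas[["wn"]], 2 * g$areas[["wn"]])
  expect_equal(g2$chi_n, 2 * g$chi_n)
  expect_equal(g2$K_n_wn, g$K_n_wn)
  expect_error(sphere_pack_state(1e12, 1e-4), "too high")
})

test_that("Gauss-Bonnet accounting closes on sphere packs", {
  g <- sphere_pack_state(2e9, 1e-4)
  expect_lt(abs(gauss_bonnet_residual(g)),
            1e-12 * 4 * pi * g$chi_n)
  empty <- geometry_state(eps = c(w = 1, n = 0, s = 0),
                          areas = c(wn = 0, ws = 0, ns = 0))
  expect_equal(gauss_bonnet_residual(empty), 0)
  # perturbing K by delta shifts the residual by -eps_wn * delta
  delta <- 1e5
  g2 <- g; g2$K_n_wn <- g$K_n_wn + delta
  expect_equal(gauss_bonnet_residual(g2) - gauss_bonnet_residual(g),
               -g$areas[["wn"]] * delta)
})

test_that("interfacial-area relaxation follows the scalar exponential", {
  base <- geometry_state(eps = c(w = 0.6, n = 0.1, s = 0.3),
                         areas = c(wn = 0, ws = 10, ns = 5),
                         J_w_wn = 1e4, chi_s_ws = 0.5)
  # equilibrium: everything static at eps_eq
  eqst <- base; eqst$areas[["wn"]] <- 0.1
  expect_equal(interfacial_area_rate(eqst, 0, 0, 0, eps_eq = 0.1, k_wn = 2),
               0)
  # pure relaxation integrates to eps_eq (1 - exp(-k t))
  rhs <- function(t, y, p) {
    s <- base; s$areas[["wn"]] <- y
    list(interfacial_area_rate(s, 0, 0, 0, eps_eq = 0.1, k_wn = 2))
  }
  sol <- deSolve::ode(0, c(0, 1, 2.5), rhs, NULL, rtol = 1e-12,
                      atol = 1e-14)
  expect_equal(unname(sol[2, 2]), 0.1 * (1 - exp(-2)), tolerance = 1e-6)
  expect_equal(unname(sol[3, 2]), 0.1 * (1 - exp(-5)), tolerance = 1e-6)
  # geometric term isolation: frozen wetting fraction, rate q
  q <- 3e-4
  expect_equal(interfacial_area_rate(eqst, deps_w_dt = q, 0, 0,
                                     eps_eq = eqst$areas[["wn"]], k_wn = 2),
               1e4 * q)
  # wetting-rate term carries cos(phi) (eps_ws + eps_ns)
  st2 <- eqst; st2$contact_angle <- pi / 3
  expect_equal(interfacial_area_rate(st2, 0, 0, dchi_dt = 1e-3,
                                     eps_eq = st2$areas[["wn"]], k_wn = 0),
               cos(pi / 3) * 15 * 1e-3)
})

test_that("curvature evolution conserves the area-curvature product", {
  g <- sphere_pack_state(2e9, 1e-4)
  expect_equal(curvature_rate_0d(g, 0), 0)
  rate <- 5e-3
  dK <- curvature_rate_0d(g, rate)
  # d(eps_wn K)/dt = K * rate + eps_wn * dK = 0
  expect_equal(g$K_n_wn * rate + g$areas[["wn"]] * dK, 0)
  g0 <- g; g0$areas[["wn"]] <- 0
  expect_error(curvature_rate_0d(g0, rate), "topological")
})

test_that("interface normal velocity follows the averaging-theorem form", {
  expect_equal(interface_normal_velocity(0, 0.5, 10), 0)
  # hand evaluation, isotropic <n> = 0
  expect_equal(interface_normal_velocity(2e-3, 0.4, 10),
               -2e-3 * 0.4 / 100)
  # sign flips with the volume-fraction rate
  expect_equal(interface_normal_velocity(-2e-3, 0.4, 10),
               2e-3 * 0.4 / 100)
  # explicit mean normal enters additively
  expect_equal(interface_normal_velocity(1e-3, 0.4, 10, mean_normal = 0.1),
               -1e-3 * 0.5 / 100)
  expect_error(interface_normal_velocity(1e-3, 0.4, 0), "zero interfacial")
})

test_that("the Galilean residual vanishes where it must and converges to the
           analytic residual on smooth fields", {
  # homogeneous state
  x <- seq(0, 1, length.out = 21)
  expect_equal(max(abs(galilean_residual(x, rep(1, 21), rep(2, 21),
                                         rep(3, 21), rep(0.1, 21)))), 0)
  # linear eps_n with zero curvature and constant eps_wn J: residual 0
  expect_lt(max(abs(galilean_residual(x, rep(1, 21), rep(2, 21),
                                      rep(0, 21), 0.1 + 0 * x))), 1e-12)
  # trigonometric fields: compare with independently coded analytic result
  k <- 2 * pi
  fields <- function(x) list(
    ewn = 2 + sin(k * x), J = 1 + 0.5 * cos(k * x),
    K = 3 + 0.2 * sin(k * x), en = 0.3 + 0.1 * cos(k * x))
  analytic <- function(x, G = 1 / 3) {
    # -d/dx[ewn J (1-2G)] + 2 K en' - (1-G) en''
    d_ewnJ <- (cos(k * x) * k) * (1 + 0.5 * cos(k * x)) +
      (2 + sin(k * x)) * (-0.5 * sin(k * x) * k)
    en1 <- -0.1 * sin(k * x) * k
    en2 <- -0.1 * cos(k * x) * k^2
    -(1 - 2 * G) * d_ewnJ + 2 * (3 + 0.2 * sin(k * x)) * en1 -
      (1 - G) * en2
  }
  err <- vapply(c(41, 81, 161), function(n) {
    x <- seq(0, 1, length.out = n)
    f <- fields(x)
    r <- galilean_residual(x, f$ewn, f$J, f$K, f$en)
    max(abs(r - analytic(x[2:(n - 1)])))
  }, numeric(1))
  expect_true(all(diff(err) < 0))            # converging
  expect_gt(log2(err[1] / err[2]), 1.8)      # ~second order
})

test_that("the state-function fit recovers the sphere-pack family exactly", {
  grid <- expand.grid(N = c(2e8, 5e8, 1e9, 2e9, 4e9, 8e9),
                      r = c(3e-5, 5e-5, 8e-5, 1.2e-4, 1.6e-4, 2e-4))
  grid <- grid[4 / 3 * pi * grid$r^3 * grid$N < 0.25, ]
  ds <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- sphere_pack_state(grid$N[i], grid$r[i])
    data.frame(a1 = g$areas[["wn"]] + g$areas[["ns"]],
               a2 = g$areas[["wn"]] * g$J_w_wn,
               chi = g$chi_n, eps_n = g$eps[["n"]])
  }))
  f <- fit_state_function(ds)
  expect_lt(max(abs(f$residuals / ds$eps_n)), 1e-6)
  # constant dataset: constant predictor
  dc <- data.frame(a1 = rep(2, 31), a2 = 3, chi = 4, eps_n = 0.1)
  fc <- fit_state_function(dc)
  expect_equal(fc$predict(2, 3, 4), 0.1)
  # permutation invariance
  set.seed(3)
  f2 <- fit_state_function(ds[sample(nrow(ds)), ])
  expect_equal(f2$predict(ds$a1, ds$a2, ds$chi),
               f$predict(ds$a1, ds$a2, ds$chi), tolerance = 1e-10)
  # a varying response that the arguments cannot pin is degenerate
  dd <- data.frame(a1 = rep(1, 31), a2 = 1, chi = 1,
                   eps_n = seq(0.1, 0.2, length.out = 31))
  expect_error(fit_state_function(dd, family = "polynomial"), "degenerate")
  expect_error(fit_state_function(ds[1:10, ]), "at least 30")
})
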