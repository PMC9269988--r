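## Three-phase geometric state and evolution: interfacial areas, mean and
## Gaussian curvatures, Gauss-Bonnet accounting, the integral-geometry
## state function, and the well-mixed (0-D) three-phase dynamical system.

#' Three-phase geometric state
#'
#' Macroscale geometric densities: volume fractions, specific interfacial
#' areas (1/m), interface mean curvature `J_w_wn` and solid-surface mean
#' curvature `J_s_ss` (1/m, a single solid curvature shared by the ws and
#' ns interfaces), Gaussian curvatures (1/m^2), Euler-characteristic
#' density `chi_n` (1/m^3), solid-surface wetted fraction `chi_s_ws`, and
#' the constant contact angle.
#'
#' @param eps named volume fractions `c(w = , n = , s = )` summing to 1.
#' @param areas named specific areas `c(wn = , ws = , ns = )` (1/m).
#' @param J_w_wn fluid-fluid interface mean curvature (1/m).
#' @param K_n_wn Gaussian curvature of the wn interface (1/m^2).
#' @param K_n_ns Gaussian curvature of the ns interface (1/m^2).
#' @param chi_n Euler-characteristic density of the non-wetting phase
#'   (1/m^3).
#' @param chi_s_ws wetted fraction of the solid surface, in \[0, 1\].
#' @param J_s_ss solid-surface mean curvature (1/m).
#' @param contact_angle contact angle through the wetting phase (rad).
#' @return object of class `geometry_state`.
#' @export
geometry_state <- function(eps, areas, J_w_wn = 0, K_n_wn = 0, K_n_ns = 0,
                           chi_n = 0, chi_s_ws = 1, J_s_ss = 0,
                           contact_angle = 0) {
  if (abs(sum(eps) - 1) > 1e-10)
    stop("volume fractions must sum to 1")
  if (any(areas < 0)) stop("specific interfacial areas must be nonnegative")
  if (chi_s_ws < 0 || chi_s_ws > 1) stop("chi_s_ws must lie in [0, 1]")
  structure(list(eps = eps, areas = areas, J_w_wn = J_w_wn,
                 K_n_wn = K_n_wn, K_n_ns = K_n_ns, chi_n = chi_n,
                 chi_s_ws = chi_s_ws, J_s_ss = J_s_ss,
                 contact_angle = contact_angle),
            class = "geometry_state")
}

#' @export
print.geometry_state <- function(x, ...) {
  cat(sprintf(paste0("<geometry_state> eps(w,n,s)=(%.3g, %.3g, %.3g), ",
                     "eps_wn=%.3g 1/m, J=%.3g 1/m, K=%.3g 1/m^2\n"),
              x$eps[["w"]], x$eps[["n"]], x$eps[["s"]],
              x$areas[["wn"]], x$J_w_wn, x$K_n_wn))
  invisible(x)
}

#' Geometry of a dilute monodisperse sphere pack
#'
#' Non-overlapping spheres of the non-wetting phase in a wetting bath:
#' `eps_n = 4/3 pi r^3 N`, `eps_wn = 4 pi r^2 N`, `J = 2/r`, `K = 1/r^2`,
#' `chi_n = N`.  The dilute assumption requires `eps_n < 0.3`.
#'
#' @param number_density spheres per volume `N` (1/m^3).
#' @param radius sphere radius (m).
#' @param eps_s solid volume fraction of the embedding medium (default 0).
#' @return a [geometry_state()].
#' @export
sphere_pack_state <- function(number_density, radius, eps_s = 0) {
  if (number_density < 0 || radius <= 0)
    stop("need number_density >= 0 and radius > 0")
  eps_n <- 4 / 3 * pi * radius^3 * number_density
  if (eps_n >= 0.3)
    stop("packing fraction ", format(eps_n, digits = 4),
         " too high for the dilute sphere-pack model (< 0.3)")
  geometry_state(
    eps = c(w = 1 - eps_n - eps_s, n = eps_n, s = eps_s),
    areas = c(wn = 4 * pi * radius^2 * number_density, ws = 0, ns = 0),
    J_w_wn = if (number_density > 0) 2 / radius else 0,
    K_n_wn = if (number_density > 0) 1 / radius^2 else 0,
    K_n_ns = 0, chi_n = number_density, chi_s_ws = 1)
}

#' Gauss-Bonnet residual
#'
#' For smooth closed non-wetting-phase boundaries the Euler characteristic
#' links area-weighted Gaussian curvatures:
#' `4 pi chi_n = eps_wn K_n_wn + eps_ns K_n_ns`.  Returns the residual of
#' that identity (1/m^3).
#'
#' @param state a [geometry_state()].
#' @return residual `4 pi chi_n - (eps_wn K_wn + eps_ns K_ns)`.
#' @export
gauss_bonnet_residual <- function(state) {
  4 * pi * state$chi_n -
    (state$areas[["wn"]] * state$K_n_wn + state$areas[["ns"]] * state$K_n_ns)
}

#' Fluid-fluid interfacial-area evolution rate (well-mixed reduction)
#'
#' `d eps_wn/dt = J_w_wn (d eps_w/dt + chi_s_ws d eps_s/dt)
#'  + k_wn (eps_eq - eps_wn) + cos(phi) (eps_ws + eps_ns) d chi_s_ws/dt`,
#' the spatial transport and strain terms vanishing in the well-mixed
#' limit and common-curve contributions dropped.
#'
#' @param state a [geometry_state()].
#' @param deps_w_dt,deps_s_dt volume-fraction rates (1/s).
#' @param dchi_dt wetted-fraction rate (1/s).
#' @param eps_eq equilibrium specific interfacial area (1/m).
#' @param k_wn nonnegative area-relaxation rate (1/s).
#' @return area rate in 1/(m s).
#' @export
interfacial_area_rate <- function(state, deps_w_dt = 0, deps_s_dt = 0,
                                  dchi_dt = 0, eps_eq, k_wn) {
  if (k_wn < 0) stop("area relaxation rate must be nonnegative")
  state$J_w_wn * (deps_w_dt + state$chi_s_ws * deps_s_dt) +
    k_wn * (eps_eq - state$areas[["wn"]]) +
    cos(state$contact_angle) * (state$areas[["ws"]] + state$areas[["ns"]]) *
      dchi_dt
}

#' Gaussian-curvature evolution in the well-mixed limit
#'
#' The curvature evolution reduces to conservation of the product
#' `eps_wn * K`: `dK/dt = -K (d eps_wn/dt) / eps_wn`.  A vanishing
#' interfacial area is a topological change this model does not represent
#' and raises an error.
#'
#' @param state a [geometry_state()].
#' @param area_rate `d eps_wn/dt` (1/(m s)).
#' @return `dK/dt` in 1/(m^2 s).
#' @export
curvature_rate_0d <- function(state, area_rate) {
  if (state$areas[["wn"]] <= 0)
    stop("vanishing interfacial area: topological change not modeled")
  -state$K_n_wn * area_rate / state$areas[["wn"]]
}

#' Normal velocity of the fluid-fluid interface
#'
#' Averaging-theorem approximation
#' `eps_wn^2 w_wn = -(d eps_w/dt) (grad eps_w + <n_w>)`; the average
#' interface normal `<n_w>` vanishes in the isotropic case.
#'
#' @param deps_w_dt time rate of the wetting volume fraction (1/s).
#' @param grad_eps_w spatial gradient of the wetting volume fraction (1/m).
#' @param area specific interfacial area `eps_wn` (1/m).
#' @param mean_normal average interface normal (default 0, isotropic).
#' @return interface normal velocity (m/s), same shape as `grad_eps_w`.
#' @export
interface_normal_velocity <- function(deps_w_dt, grad_eps_w, area,
                                      mean_normal = 0) {
  if (area <= 0) {
    if (any(deps_w_dt != 0))
      stop("zero interfacial area with nonzero volume-fraction rate")
    return(grad_eps_w * 0)
  }
  -deps_w_dt * (grad_eps_w + mean_normal) / area^2
}

#' Galilean-invariance residual of the mean-curvature constraint (1-D)
#'
#' Discrete residual of the constraint
#' `-d/dx[eps_wn J (1 - 2G)] + 2 K d(eps_n)/dx - d2/dx2[(1 - G) eps_n]`
#' on the interior nodes of a 1-D grid (central differences), with `G` the
#' axial component of the orientation tensor (isotropic: 1/3).  Spatially
#' uniform fields give an identically zero residual.
#'
#' @param x strictly increasing node coordinates (uniform spacing).
#' @param eps_wn,J,K,eps_n fields at the nodes.
#' @param G axial orientation component (default 1/3).
#' @return residual at nodes `2..(n-1)`.
#' @export
galilean_residual <- function(x, eps_wn, J, K, eps_n, G = 1 / 3) {
  n <- length(x)
  if (n < 3) stop("need at least three nodes")
  h <- diff(x)
  if (max(abs(h - h[1])) > 1e-12 * h[1]) stop("grid must be uniform")
  h <- h[1]
  i <- 2:(n - 1)
  f1 <- eps_wn * J * (1 - 2 * G)
  d1 <- (f1[i + 1] - f1[i - 1]) / (2 * h)
  dn <- (eps_n[i + 1] - eps_n[i - 1]) / (2 * h)
  d2 <- (1 - G) * (eps_n[i + 1] - 2 * eps_n[i] + eps_n[i - 1]) / h^2
  -d1 + 2 * K[i] * dn - d2
}

#' Fit the integral-geometry state function
#'
#' Fits the smooth state relation `eps_n = F(a1, a2, chi)` with arguments
#' `a1 = eps_wn + eps_ns`, `a2 = eps_wn J_w_wn + eps_ns J_s_ns` and the
#' Euler-characteristic density.  The default `log-linear` family is a
#' polynomial in the logarithms of the (positive) arguments, which contains
#' the dilute sphere-pack family exactly; `polynomial` fits a polynomial in
#' the raw arguments.
#'
#' @param dataset data frame with columns `a1`, `a2`, `chi`, `eps_n`
#'   (>= 30 rows spanning the argument ranges).
#' @param family `"loglinear"` or `"polynomial"`.
#' @param degree polynomial degree.
#' @return object of class `state_function` with `predict` method; carries
#'   in-sample residuals.
#' @export
fit_state_function <- function(dataset, family = c("loglinear", "polynomial"),
                               degree = 1) {
  family <- match.arg(family)
  need <- c("a1", "a2", "chi", "eps_n")
  if (!all(need %in% names(dataset)))
    stop("dataset must have columns ", paste(need, collapse = ", "))
  if (nrow(dataset) < 30) stop("need at least 30 states")
  if (family == "loglinear" &&
      any(dataset$a1 <= 0 | dataset$a2 <= 0 | dataset$chi <= 0 |
          dataset$eps_n <= 0))
    stop("loglinear family requires positive arguments")
  tf <- if (family == "loglinear") log else identity
  design <- function(a1, a2, chi) {
    X <- matrix(1, length(a1), 1)
    for (v in list(tf(a1), tf(a2), tf(chi)))
      for (p in seq_len(degree)) X <- cbind(X, v^p)
    X
  }
  X <- design(dataset$a1, dataset$a2, dataset$chi)
  y <- tf(dataset$eps_n)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  resid_y <- y - as.vector(X %*% beta)
  ## a rank-deficient span is an error only when it fails to pin the
  ## response (an exactly-representable family, e.g. sphere packs in log
  ## space, may be collinear yet fit exactly; a constant dataset fits its
  ## mean)
  if (fit$rank < ncol(X) &&
      max(abs(resid_y)) > 1e-8 * max(1, max(abs(y))) &&
      stats::sd(y) > 0)
    stop("degenerate argument span: state-function design is rank-deficient")
  pred <- function(a1, a2, chi) {
    p <- as.vector(design(a1, a2, chi) %*% beta)
    if (family == "loglinear") exp(p) else p
  }
  structure(list(coefficients = beta, family = family, degree = degree,
                 rank = fit$rank, predict = pred,
                 residuals = dataset$eps_n - pred(dataset$a1, dataset$a2,
                                                  dataset$chi)),
            class = "state_function")
}

#' @export
print.state_function <- function(x, ...) {
  cat(sprintf("<state_function> family=%s degree=%d, max |resid| = %.3g\n",
              x$family, x$degree, max(abs(x$residuals))))
  invisible(x)
}

#' Predict from a fitted state function
#' @param object a `state_function`.
#' @param a1,a2,chi argument vectors.
#' @param ... ignored.
#' @return predicted `eps_n`.
#' @export
predict.state_function <- function(object, a1, a2, chi, ...) {
  object$predict(a1, a2, chi)
}
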