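## Coefficient recovery from synthetic trajectories by trajectory-matching
## least squares.

#' Recover a mass-transfer coefficient from an observed trajectory
#'
#' Re-simulates the scenario over a log-spaced coefficient range and
#' minimizes the sum of squared deviations between the observed and
#' simulated fluid-phase solute mass fraction.
#'
#' @param times observation times (s).
#' @param observed observed fluid solute mass fractions at `times`.
#' @param config a transfer scenario ([build_transfer_fixture()] shape); the
#'   first transfer's coefficient is the fitted parameter.
#' @param species solute species symbol (default the transferred species).
#' @param interval search interval for the coefficient (log-scale search).
#' @return list with `estimate`, `objective`.
#' @export
recover_transfer_coeff <- function(times, observed, config,
                                   species = NULL,
                                   interval = c(1e-8, 1e-4)) {
  if (is.null(species)) species <- config$transfers[[1]]$species
  config$solver$rtol <- max(config$solver$rtol, 1e-7)
  config$solver$atol <- max(config$solver$atol, 1e-11)
  obj <- function(lk) {
    cfg <- config
    cfg$transfers[[1]]$transfer_coeff <- 10^lk
    res <- simulate2p(cfg, times, diagnostics = FALSE)
    sim <- res$omega_f[, 1, species]
    sum((sim - observed)^2)
  }
  opt <- stats::optimize(obj, interval = log10(interval), tol = 3e-4)
  list(estimate = 10^opt$minimum, objective = opt$objective)
}

#' Recover a reaction rate coefficient from an observed trajectory
#'
#' As [recover_transfer_coeff()], fitting the first reaction's rate
#' coefficient against the observed solid-phase mass fraction of a marker
#' species.
#'
#' @param times observation times (s).
#' @param observed observed solid mass fractions of `species` at `times`.
#' @param config a reaction scenario ([build_reaction_fixture()] shape).
#' @param species marker species (default `"l"`).
#' @param interval search interval for the coefficient.
#' @return list with `estimate`, `objective`.
#' @export
recover_reaction_coeff <- function(times, observed, config, species = "l",
                                   interval = c(1e-9, 1e-5)) {
  config$solver$rtol <- max(config$solver$rtol, 1e-7)
  config$solver$atol <- max(config$solver$atol, 1e-11)
  obj <- function(lk) {
    cfg <- config
    cfg$reactions[[1]]$rate_coeff <- 10^lk
    res <- simulate2p(cfg, times, diagnostics = FALSE)
    sim <- res$omega_s[, 1, species]
    sum((sim - observed)^2)
  }
  opt <- stats::optimize(obj, interval = log10(interval), tol = 3e-4)
  list(estimate = 10^opt$minimum, objective = opt$objective)
}
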