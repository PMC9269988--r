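## Shared helpers: tiny species tables and independent oracle utilities.

toy_species <- function() species_table(c(a = 0.018, b = 0.180))

lysis_species <- function() species_table(c(n = 0.1, e = 0.06, w = 0.018))

## Independent trapezoid quadrature.
trapz <- function(t, f) sum(diff(t) * (f[-1] + f[-length(f)]) / 2)

## Pack the initial state of a two-phase scenario.
initial_packed <- function(cfg) {
  tcatsim:::pack_state_2p(cfg, cfg$initial$eps_s, cfg$initial$omega_f,
                          cfg$initial$omega_s)
}

min_ledger_group <- function(result) {
  min(vapply(result$diagnostics,
             function(d) min(unclass(d$ledger)), numeric(1)))
}
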