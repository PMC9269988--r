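## Scenario configuration files (YAML; JSON accepted), result
## serialization and run manifests.

#' Load a two-phase scenario configuration file
#'
#' Reads a YAML (or JSON) scenario description, validates it against the
#' schema shipped at `inst/extdata/scenario-schema.yaml`, resolves
#' defaults, and builds a [scenario_2p()].  Schema violations are reported
#' together, each with its key path.
#'
#' @param path configuration file.
#' @return a [scenario_2p()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  errs <- character(0)
  need <- function(key, test, msg) {
    v <- raw[[key]]
    if (is.null(v) || !test(v)) errs <<- c(errs, paste0(key, ": ", msg))
  }
  need("grid", is.list, "missing grid block")
  need("species", is.list, "missing species block (molar_mass map)")
  need("phases", is.list, "missing phases block")
  need("initial", is.list, "missing initial block")
  if (!is.null(raw$reactions)) {
    for (i in seq_along(raw$reactions)) {
      rx <- raw$reactions[[i]]
      if (!is.null(rx$rate_coeff) && rx$rate_coeff < 0)
        errs <- c(errs, sprintf("reactions[%d].rate_coeff: negative", i))
    }
  }
  if (!is.null(raw$transfers)) {
    for (i in seq_along(raw$transfers)) {
      tr <- raw$transfers[[i]]
      if (!is.null(tr$transfer_coeff) && tr$transfer_coeff < 0)
        errs <- c(errs, sprintf("transfers[%d].transfer_coeff: negative", i))
    }
  }
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  num_map <- function(x) {
    v <- unlist(x)
    if (is.null(v)) return(NULL)
    stats::setNames(as.numeric(v), names(v))
  }
  species <- species_table(num_map(raw$species$molar_mass))
  phases <- lapply(names(raw$phases), function(ph) {
    p <- raw$phases[[ph]]
    phase_def(ph, unlist(p$members), p$reference_species, species)
  })
  names(phases) <- names(raw$phases)
  th <- raw$thermo
  if (is.null(th)) th <- list()
  mu0 <- if (is.null(th$mu0)) list() else lapply(th$mu0, num_map)
  thermo <- thermo_params(
    temperature = th$temperature %||% 310,
    gas_constant = th$gas_constant %||% 8.314,
    mu0 = mu0,
    x_floor = th$x_floor %||% 1e-12)
  g <- raw$grid
  grid <- if (!is.null(g$edges)) grid_1d(num(g$edges),
                                         g$geometry %||% "cartesian")
  else uniform_grid(as.integer(g$n_cells), as.numeric(g$length),
                    g$geometry %||% "cartesian")
  reactions <- lapply(raw$reactions %||% list(), function(rx) {
    st <- num_map(rx$stoich)
    if (!is.null(rx$free_species))
      st <- balance_stoichiometry(st, rx$free_species, species)
    reaction_spec(rx$id %||% "reaction", rx$phase %||% "s", st,
                  rx$rate_coeff %||% 0)
  })
  transfers <- lapply(raw$transfers %||% list(), function(tr)
    transfer_spec(tr$species, tr$donor, tr$receiver,
                  as.numeric(tr$transfer_coeff)))
  cf <- raw$coeffs %||% list()
  coeffs <- closure_coeffs(
    diffusivity = lapply(cf$diffusivity %||% list(), num_map),
    resistance = lapply(cf$resistance %||% list(), num_map),
    compressibility = as.numeric(cf$compressibility %||% 0),
    tension = num_map(cf$tension) %||% numeric(0),
    area_relaxation = as.numeric(cf$area_relaxation %||% 0),
    capillary_relaxation = as.numeric(cf$capillary_relaxation %||% 0))
  init <- raw$initial
  n <- grid$n
  fill_omega <- function(om_list, members) {
    om <- matrix(0, n, length(members), dimnames = list(NULL, members))
    for (sp in names(om_list)) {
      v <- as.numeric(unlist(om_list[[sp]]))
      om[, sp] <- if (length(v) == 1) rep(v, n) else v
    }
    om
  }
  omega_f <- fill_omega(init$omega_f, phases$f$members)
  omega_s <- fill_omega(init$omega_s, phases$s$members)
  eps_s <- num(init$eps_s)
  if (length(eps_s) == 1) eps_s <- rep(eps_s, n)
  bcr <- raw$bc %||% list()
  bc <- list(
    pressure = list(outer = as.numeric(bcr$pressure$outer %||% 0),
                    inner = as.numeric(bcr$pressure$inner %||% NA)),
    species = lapply(bcr$species %||% list(), function(b)
      list(type = b$type %||% "noflux", value = b$value %||% NA)),
    gauge_cell = bcr$gauge_cell)
  sv <- raw$solver %||% list()
  scenario_2p(grid = grid, species = species, phases = phases,
              thermo = thermo,
              densities = num_map(raw$densities %||% c(f = 1000, s = 1050)),
              reactions = reactions, transfers = transfers, coeffs = coeffs,
              initial = list(eps_s = eps_s, omega_f = omega_f,
                             omega_s = omega_s),
              bc = bc,
              body_potential = num_map(raw$body_potential %||%
                                         c(f = 0, s = 0)),
              gravity = as.numeric(raw$gravity %||% 0),
              solver = list(rtol = sv$rtol %||% 1e-8,
                            atol = sv$atol %||% 1e-10,
                            method = sv$method %||% "lsodes"),
              seed = raw$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a scenario configuration to YAML
#'
#' Writes a YAML document that [load_config()] reads back into a
#' semantically identical scenario (functions such as modulation factors
#' are not serializable and are omitted).
#'
#' @param config a [scenario_2p()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  doc <- list(
    grid = list(edges = as.numeric(config$grid$edges),
                geometry = config$grid$geometry),
    species = list(molar_mass = as.list(config$species$molar_mass)),
    phases = lapply(config$phases, function(p)
      list(members = p$members, reference_species = p$reference_species)),
    thermo = list(temperature = config$thermo$temperature,
                  gas_constant = config$thermo$gas_constant,
                  x_floor = config$thermo$x_floor,
                  mu0 = lapply(config$thermo$mu0, as.list)),
    densities = as.list(config$densities),
    reactions = lapply(config$reactions, function(rx)
      list(id = rx$id, phase = rx$phase, stoich = as.list(rx$stoich),
           rate_coeff = rx$rate_coeff)),
    transfers = lapply(config$transfers, function(tr)
      list(species = tr$species, donor = tr$donor, receiver = tr$receiver,
           transfer_coeff = tr$transfer_coeff)),
    coeffs = list(diffusivity = lapply(config$coeffs$diffusivity, as.list),
                  resistance = lapply(config$coeffs$resistance, as.list),
                  compressibility = config$coeffs$compressibility,
                  tension = as.list(config$coeffs$tension),
                  area_relaxation = config$coeffs$area_relaxation,
                  capillary_relaxation = config$coeffs$capillary_relaxation),
    initial = list(eps_s = as.numeric(config$initial$eps_s),
                   omega_f = apply(config$initial$omega_f, 2, as.numeric,
                                   simplify = FALSE),
                   omega_s = apply(config$initial$omega_s, 2, as.numeric,
                                   simplify = FALSE)),
    bc = list(
      pressure = list(
        outer = if (is.na(config$bc$pressure$outer)) NA
                else as.numeric(config$bc$pressure$outer),
        inner = if (is.na(config$bc$pressure$inner)) NA
                else as.numeric(config$bc$pressure$inner)),
      species = config$bc$species,
      gauge_cell = config$bc$gauge_cell),
    body_potential = as.list(config$body_potential),
    gravity = config$gravity,
    solver = config$solver,
    seed = config$seed)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Write simulation results to a directory
#'
#' Emits deterministic CSV tables (time series of species masses, entropy
#' ledger, fields at the final time) plus a JSON run manifest listing every
#' file written, the config hash and the seed.  Rerunning with an identical
#' config and seed reproduces byte-identical tables.
#'
#' @param result a `sim_result_2p`.
#' @param out_dir output directory (created if needed).
#' @param formats subset of `"csv"` (field snapshots are CSV; no binary
#'   containers are written).
#' @return the run manifest, invisibly.
#' @export
write_result <- function(result, out_dir, formats = "csv") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     p, row.names = FALSE, quote = FALSE)
    files <<- c(files, name)
    p
  }
  nt <- length(result$times)
  fph <- result$config$phases$f; sph <- result$config$phases$s
  mass_tab <- data.frame(time = result$times)
  for (sp in fph$members)
    mass_tab[[paste0("mass_f_", sp)]] <-
      vapply(result$diagnostics, function(d) d$mass_f[[sp]], numeric(1))
  for (sp in sph$members)
    mass_tab[[paste0("mass_s_", sp)]] <-
      vapply(result$diagnostics, function(d) d$mass_s[[sp]], numeric(1))
  wr(mass_tab, "species_mass.csv")
  led <- do.call(rbind, lapply(result$diagnostics, function(d)
    as.data.frame(t(unclass(d$ledger)))))
  led <- cbind(time = result$times, led,
               total = vapply(result$diagnostics,
                              function(d) ledger_total(d$ledger), numeric(1)))
  wr(led, "entropy_ledger.csv")
  final <- data.frame(r = result$config$grid$centers,
                      eps_s = result$eps_s[nt, ],
                      pressure = result$pressure[nt, ])
  for (sp in fph$members) final[[paste0("omega_f_", sp)]] <-
    result$omega_f[nt, , sp]
  for (sp in sph$members) final[[paste0("omega_s_", sp)]] <-
    result$omega_s[nt, , sp]
  wr(final, "final_fields.csv")
  cfg_file <- file.path(out_dir, "config.yaml")
  write_config(result$config, cfg_file)
  files <- c(files, "config.yaml")
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = result$seed,
                   package_version =
                     as.character(utils::packageVersion("tcatsim")),
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
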