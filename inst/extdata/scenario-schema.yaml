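# Schema for two-phase scenario configuration files read by load_config().
# Types: map = YAML mapping, seq = sequence.  SI units throughout.
grid:                      # required
  geometry: cartesian | spherical       # default cartesian
  edges: seq of numbers (m)             # either edges, or n_cells + length
  n_cells: integer
  length: number (m)                    # outer radius when spherical
species:                   # required
  molar_mass: map species -> kg/mol     # strictly positive
phases:                    # required; keys f (fluid) and s (solid)
  f: {members: seq of species, reference_species: species}
  s: {members: seq of species, reference_species: species}
thermo:
  temperature: number (K, default 310)
  gas_constant: number (J/(mol K), default 8.314)
  x_floor: number in (0, 1e-6], default 1e-12
  mu0: map phase -> map species -> J/kg (default 0)
densities: {f: kg/m^3, s: kg/m^3}       # default 1000 / 1050
reactions:                 # optional sequence
  - id: string
    phase: f | s
    stoich: map species -> signed molar coefficient (reactants negative)
    free_species: species                # optional; solved for mass balance
    rate_coeff: number >= 0
transfers:                 # optional sequence
  - {species: string, donor: f|s, receiver: f|s, transfer_coeff: number >= 0}
coeffs:
  diffusivity: map phase -> map species -> m^2/s
  resistance: {f: number > 0}           # Darcy resistance
  compressibility: number >= 0
  tension: map interface -> N/m
  area_relaxation: number >= 0 (1/s)
  capillary_relaxation: number >= 0
initial:                   # required
  eps_s: number or seq per cell, in [0, 1]
  omega_f: map species -> number or seq (rows sum to 1 with the rest)
  omega_s: map species -> number or seq
bc:
  pressure: {outer: Pa or null, inner: Pa or null}   # null = no-flux
  gauge_cell: integer                    # required when both sides no-flux
  species:                               # outer-boundary fluid conditions
    <species>: {type: dirichlet | noflux, value: mass fraction}
body_potential: {f: J/kg, s: J/kg}
gravity: number (m/s^2, axial)
solver: {rtol: number, atol: number, method: deSolve method name}
seed: integer
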