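## Shared fixtures, built in code.

default_grid <- function() grid_spec()

## fields with optional uniform concentrations and zero flow
make_fields <- function(grid = default_grid(),
                        metabolites = default_metabolites(),
                        init = c(lactose = 1e-3)) {
  field_set(grid, metabolites, init_conc = init)
}

## a cell table at given positions (um), all mass 1
make_cells <- function(position, species = NULL,
                       params = default_species()) {
  if (is.null(species)) {
    species <- rep(c("ECOLI", "SENTERICA"), length.out = nrow(position))
  }
  new_cells(species, position, params)
}

## hand-written Sherwood correlation, independent of the package path
sherwood_by_hand <- function(eps, Re, Sc) {
  (7 - 10 * eps + 5 * eps^2) * (1 + 0.17 * Re^0.2 * Sc^(1 / 3)) +
    (1.33 - 2.31 * eps + 1.16 * eps^2) * Re^0.7 * Sc^(1 / 3)
}

## quick scenario helper
quick_config <- function(..., duration = 10) {
  scenario_config(duration = duration, ...)
}
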