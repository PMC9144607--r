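## Core domain types: species parameters, metabolites, physical environment,
## parcel grid, field set, and the agent (cell) table.

#' Equivalent Stokes radius of a cell
#'
#' Converts a cell volume to the radius of the sphere of equal volume,
#' `r = (3 V / (4 pi))^(1/3)`.  Rod-shaped cells are represented in the
#' mechanics as this equivalent sphere.
#'
#' @param V_cell cell volume(s), um^3. Must be positive.
#' @return radius in um.
#' @examples
#' stokes_radius(4 * pi / 3)  # unit sphere -> 1
#' @export
stokes_radius <- function(V_cell) {
  if (any(!is.finite(V_cell)) || any(V_cell <= 0)) {
    stop("stokes_radius: V_cell must be positive and finite")
  }
  (3 * V_cell / (4 * pi))^(1 / 3)
}

#' Nondimensionalize a biomass by the standard cell mass
#'
#' @param mass_kg biomass in kg.
#' @param standard_cell_mass mass of one standard cell, kg.
#' @return biomass in cell equivalents (1 = one standard cell).
#' @export
cell_equivalents <- function(mass_kg, standard_cell_mass) {
  if (!is.finite(standard_cell_mass) || standard_cell_mass <= 0) {
    stop("cell_equivalents: standard_cell_mass must be positive")
  }
  mass_kg / standard_cell_mass
}

#' Per-species biological parameters
#'
#' `rho_c_ce` is the biomass density of a cell expressed in cell equivalents
#' per um^3; because one cell equivalent is by definition the biomass of one
#' standard cell, `rho_c_ce = 1 / V_cell`.  `k_convert` is the zero-order
#' cross-feeding conversion rate and defaults to `mu_max`.
#'
#' @param name `"ECOLI"` or `"SENTERICA"`.
#' @param mu_max maximum specific growth rate, 1/s.
#' @param V_cell cell volume, um^3.
#' @param rho_cell_kg wet biomass density, kg/m^3 (sets the standard cell mass).
#' @param limiting_substrate,co_substrate,product metabolite names
#'   (`co_substrate` may be `NA`).
#' @param yield_product cell equivalents of product per cell equivalent of
#'   limiting substrate converted.
#' @param Y_XS biomass-substrate yield (cell equivalents biomass per cell
#'   equivalent substrate routed to growth).
#' @param k_convert zero-order conversion rate, 1/s.
#' @return an object of class `species_params`.
#' @export
species_params <- function(name,
                           mu_max,
                           V_cell,
                           rho_cell_kg = 1100,
                           limiting_substrate,
                           co_substrate = NA_character_,
                           product,
                           yield_product,
                           Y_XS = 0.5,
                           k_convert = mu_max) {
  stopifnot(name %in% c("ECOLI", "SENTERICA"))
  if (mu_max <= 0) stop("species_params: mu_max must be > 0")
  if (V_cell <= 0) stop("species_params: V_cell must be > 0")
  if (yield_product <= 0) stop("species_params: yield_product must be > 0")
  if (Y_XS <= 0) stop("species_params: Y_XS must be > 0")
  if (identical(limiting_substrate, product)) {
    stop("species_params: limiting_substrate must differ from product")
  }
  r <- stokes_radius(V_cell)
  structure(list(
    name = name,
    mu_max = mu_max,
    V_cell = V_cell,
    rho_cell_kg = rho_cell_kg,
    ## standard cell mass in kg (wet): density * volume
    m_cell_kg = rho_cell_kg * V_cell * .M_PER_UM^3,
    rho_c_ce = 1 / V_cell,     # cell equivalents / um^3
    r_um = r,
    d_c_um = 2 * r,
    limiting_substrate = limiting_substrate,
    co_substrate = co_substrate,
    product = product,
    yield_product = yield_product,
    Y_XS = Y_XS,
    k_convert = k_convert
  ), class = "species_params")
}

#' Default two-species cross-feeding parameter set
#'
#' The E. coli metB knockout (methionine-limited, lactose co-substrate,
#' acetate producer) and the methionine-secreting S. enterica
#' (acetate-limited).  Growth rates are 1.82e-5 and 9.09e-6 1/s.  The product
#' yields default to Y_AM = 1.86 (acetate per methionine, E. coli) and
#' Y_MA = 1 (methionine per acetate, S. enterica), whose ratio matches the
#' baseline 1.86:1 community composition.
#'
#' @param lambda_E,lambda_S product-yield scaling factors (1 = baseline),
#'   applied multiplicatively to Y_AM and Y_MA.
#' @return named list with elements `ECOLI` and `SENTERICA`.
#' @export
default_species <- function(lambda_E = 1, lambda_S = 1) {
  list(
    ECOLI = species_params(
      name = "ECOLI", mu_max = 1.82e-5, V_cell = 0.436,
      limiting_substrate = "methionine", co_substrate = "lactose",
      product = "acetate", yield_product = 1.86 * lambda_E
    ),
    SENTERICA = species_params(
      name = "SENTERICA", mu_max = 9.09e-6, V_cell = 0.436,
      limiting_substrate = "acetate", co_substrate = NA_character_,
      product = "methionine", yield_product = 1.0 * lambda_S
    )
  )
}

#' Metabolite specification
#'
#' @param name one of `"lactose"`, `"methionine"`, `"acetate"`.
#' @param D_M molecular diffusivity, m^2/s.
#' @param beta solutal Boussinesq expansion coefficient: fractional fluid
#'   density change per unit concentration (per cell-equivalent/um^3).
#' @param S_ref reference concentration for the Boussinesq term,
#'   cell equivalents/um^3.
#' @return an object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, D_M, beta = 0, S_ref = 0) {
  stopifnot(name %in% c("lactose", "methionine", "acetate"))
  if (D_M <= 0) stop("metabolite_spec: D_M must be > 0")
  structure(list(name = name, D_M = D_M, beta = beta, S_ref = S_ref),
            class = "metabolite_spec")
}

## Diffusivity presets (m^2/s). The intermediate value 5e-6 cm^2/s is the
## nominal setting; "biofilm" is a typical effective diffusivity in a dense
## matrix (~0.2 of the aqueous value) and "liquid" the aqueous small-molecule
## scale.
.DIFFUSIVITY_PRESETS <- c(biofilm = 1e-10, intermediate = 5e-10, liquid = 1e-9)

## Solutal expansion coefficient per (cell equivalent / um^3), identical for
## the three metabolites; calibrated once so the strongest-convection case
## (1 g floor biofilm at biofilm diffusivity) reaches the maximum cell-scale
## Peclet number ~0.05 that the study regime prescribes (see the methods
## vignette for the calibration and its rationale).
.BETA_DEFAULT <- 2.2e5

#' Default metabolite set for a named diffusivity regime
#'
#' @param diffusivity `"biofilm"`, `"intermediate"`, or `"liquid"`; or a
#'   single numeric diffusivity in m^2/s applied to all three metabolites.
#' @param beta Boussinesq expansion coefficient per (cell equivalent/um^3),
#'   shared by the three metabolites.
#' @param S_ref named reference (ambient) concentrations for the Boussinesq
#'   terms; the buoyancy force responds to deviations from these.  Defaults
#'   to the standard initial medium (lactose-only).
#' @return named list of [metabolite_spec()] (lactose, methionine, acetate).
#' @export
default_metabolites <- function(diffusivity = "intermediate",
                                beta = .BETA_DEFAULT,
                                S_ref = c(lactose = 1e-3, methionine = 0,
                                          acetate = 0)) {
  D <- if (is.numeric(diffusivity)) {
    diffusivity
  } else {
    D <- .DIFFUSIVITY_PRESETS[match.arg(diffusivity,
                                        names(.DIFFUSIVITY_PRESETS))]
    unname(D)
  }
  nm <- c("lactose", "methionine", "acetate")
  stats::setNames(lapply(nm, function(n) {
    metabolite_spec(n, D, beta = beta,
                    S_ref = if (n %in% names(S_ref)) S_ref[[n]] else 0)
  }), nm)
}

#' Physical environment: gravity mode, rotation, fluid properties
#'
#' In `"RWV"` mode the domain co-rotates with the vessel at `omega` about the
#' z axis, at a rotation-arm distance `r_B` along the (radial) y axis; the
#' lab-frame 1 g gravity vector then rotates in the body frame.  In
#' `"MICROGRAVITY"` gravity is zero and in `"ONE_G"` it points along -y.
#'
#' @param gravity_mode `"MICROGRAVITY"`, `"ONE_G"` or `"RWV"`.
#' @param rpm rotation rate, revolutions per minute (RWV only).
#' @param r_B rotation-arm length, m (RWV only).
#' @param rho_f,rho_s fluid and cell densities, kg/m^3.
#' @param nu kinematic viscosity, m^2/s.
#' @param g0 lab-frame gravitational acceleration magnitude, m/s^2.
#' @param fixed_gravity_in_body_frame if `TRUE`, the RWV body-frame gravity
#'   vector is frozen at its t = 0 orientation (sensitivity switch).
#' @return an object of class `sim_environment`.
#' @export
sim_environment <- function(gravity_mode = c("MICROGRAVITY", "ONE_G", "RWV"),
                            rpm = 10, r_B = 0.01,
                            rho_f = 1000, rho_s = 1100,
                            nu = 1e-6, g0 = 9.81,
                            fixed_gravity_in_body_frame = FALSE) {
  gravity_mode <- match.arg(gravity_mode)
  omega <- if (gravity_mode == "RWV") rpm_to_rad_s(rpm) else 0
  g_mag <- if (gravity_mode == "MICROGRAVITY") 0 else g0
  env <- structure(list(
    gravity_mode = gravity_mode,
    omega = omega, r_B = r_B,
    rho_f = rho_f, rho_s = rho_s,
    nu = nu, mu_dyn = rho_f * nu,
    g_mag = g_mag,
    fixed_gravity_in_body_frame = fixed_gravity_in_body_frame
  ), class = "sim_environment")
  validate_environment(env)
  env
}

validate_environment <- function(env) {
  stopifnot(
    abs(env$mu_dyn - env$rho_f * env$nu) <= 1e-12 * env$mu_dyn,
    env$omega == 0 || env$gravity_mode == "RWV",
    (env$g_mag == 0) == (env$gravity_mode == "MICROGRAVITY")
  )
  invisible(env)
}

#' Body-frame gravity vector at time t
#'
#' Lab gravity is along -y at t = 0.  In RWV mode the body frame rotates with
#' the vessel about z, so the gravity vector seen in the body frame rotates
#' at -omega: `g_body(t) = g0 * (-sin(omega t), -cos(omega t), 0)`.
#'
#' @param env a [sim_environment()].
#' @param t simulated time, s.
#' @return length-3 gravity vector, m/s^2.
#' @export
gravity_body <- function(env, t = 0) {
  if (env$g_mag == 0) return(c(0, 0, 0))
  if (env$gravity_mode != "RWV" || env$fixed_gravity_in_body_frame) {
    return(c(0, -env$g_mag, 0))
  }
  th <- env$omega * t
  env$g_mag * c(-sin(th), -cos(th), 0)
}

#' Uniform centrifugal body acceleration
#'
#' The centrifugal acceleration `-omega x (omega x r_B)` is approximated as a
#' uniform body force along the radial (y) axis, directed outward, i.e.
#' toward the y = 0 (outer) wall.
#'
#' @param env a [sim_environment()].
#' @return length-3 acceleration vector, m/s^2 (no buoyancy factor).
#' @export
centrifugal_accel <- function(env) {
  c(0, -env$omega^2 * env$r_B, 0)
}

#' Parcel grid specification
#'
#' The domain is a 300 x 100 x 300 um box of 5 x 20 x 5 um fluid parcels
#' (60 x 5 x 60).  x and z are periodic; y is the radial axis with wall
#' boundary conditions (y = 0 outer wall / floor, y = 100 inner wall /
#' outlet).
#'
#' @param extent_um domain extents (x, y, z), um.
#' @param parcel_um parcel dimensions (x, y, z), um.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(extent_um = c(300, 100, 300),
                      parcel_um = c(5, 20, 5)) {
  n <- extent_um / parcel_um
  if (any(abs(n - round(n)) > 1e-9)) {
    stop("grid_spec: extents must be divisible by parcel dimensions")
  }
  structure(list(
    extent_um = extent_um,
    parcel_um = parcel_um,
    n = as.integer(round(n)),
    V_parcel_um3 = prod(parcel_um),
    parcel_m = um_to_m(parcel_um)
  ), class = "grid_spec")
}

#' Metabolite and flow fields on the parcel grid
#'
#' Holds one concentration array per metabolite (cell equivalents/um^3), the
#' void-fraction field, and a staggered-grid flow state.
#'
#' @param grid a [grid_spec()].
#' @param metabolites named list of [metabolite_spec()].
#' @param init_conc named numeric of initial uniform concentrations
#'   (cell equivalents/um^3); metabolites not named start at 0.
#' @return an object of class `field_set`.
#' @export
field_set <- function(grid, metabolites,
                      init_conc = c(lactose = 1e-3)) {
  conc <- lapply(names(metabolites), function(nm) {
    v <- if (nm %in% names(init_conc)) init_conc[[nm]] else 0
    array(v, dim = grid$n)
  })
  names(conc) <- names(metabolites)
  structure(list(
    grid = grid,
    conc = conc,
    eps = array(1, dim = grid$n),
    flow = flow_state(grid)
  ), class = "field_set")
}

#' Construct the agent (cell) table
#'
#' One row per cell: position (um, body frame), velocity (m/s, body frame),
#' biomass in cell equivalents (starts at 1), intracellular
#' limiting-substrate and product pools (cell equivalents), and the fixed
#' Stokes radius.  Mass is bookkeeping; drag and exchange area use the fixed
#' radius.
#'
#' @param species character vector of species names per cell.
#' @param position n x 3 matrix of positions, um.
#' @param params species parameter list as from [default_species()].
#' @return a `data.frame` of class `cell_table`.
#' @export
new_cells <- function(species, position, params) {
  stopifnot(is.matrix(position), ncol(position) == 3,
            length(species) == nrow(position),
            all(species %in% names(params)))
  n <- length(species)
  r <- vapply(params, function(p) p$r_um, numeric(1))[species]
  z <- rep(0, n)
  cells <- data.frame(
    id = seq_len(n),
    species = as.character(species),
    x = position[, 1], y = position[, 2], z = position[, 3],
    vx = z, vy = z, vz = z,
    mass = rep(1, n),
    pool_sub = z,
    pool_pro = z,
    r_um = unname(r),
    stringsAsFactors = FALSE
  )
  class(cells) <- c("cell_table", "data.frame")
  cells
}

validate_cells <- function(cells, grid) {
  stopifnot(
    all(cells$mass > 0),
    all(cells$pool_sub >= -1e-12),
    all(cells$pool_pro >= -1e-12),
    all(cells$x >= 0 & cells$x < grid$extent_um[1]),
    all(cells$y >= 0 & cells$y <= grid$extent_um[2]),
    all(cells$z >= 0 & cells$z < grid$extent_um[3])
  )
  invisible(cells)
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params %s> mu_max=%.3g 1/s  V=%.3g um^3  r=%.3g um\n",
              x$name, x$mu_max, x$V_cell, x$r_um))
  cat(sprintf("  limiting=%s  co=%s  product=%s (yield %.3g)  Y_XS=%.3g\n",
              x$limiting_substrate, x$co_substrate, x$product,
              x$yield_product, x$Y_XS))
  invisible(x)
}

#' @export
print.sim_environment <- function(x, ...) {
  cat(sprintf("<sim_environment %s> omega=%.4g rad/s  r_B=%.3g m  |g|=%.3g m/s^2\n",
              x$gravity_mode, x$omega, x$r_B, x$g_mag))
  invisible(x)
}
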