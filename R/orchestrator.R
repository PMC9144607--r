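## The coupled time-stepping loop binding fluid, particle motion, metabolite
## transport, and growth, plus run lifecycle: configuration, state
## construction, recording, steady-state detection, and the global mass
## audit.
##
## Step ordering within one chemical step (fixed, for reproducibility):
## fluid sub-steps -> particle motion + void-fraction update -> per-cell
## kinetics (film balance, conversion, parcel draws/deposits) -> product
## film release -> scalar transport -> growth (mass update).

#' Scenario configuration
#'
#' Collects a placement recipe and every physical/numerical setting of a
#' run.  All constants that are not in the main-text parameter set
#' (yields, Boussinesq coefficients, diffusivity presets, ...) are explicit
#' arguments here so that parameter provenance is auditable.
#'
#' @param name scenario label.
#' @param placement list: `recipe` (one of `"dense_sphere"`,
#'   `"gaussian_sphere"`, `"random_uniform"`, `"two_cells"`,
#'   `"separated_colonies"`, `"floor_biofilm"`) plus recipe arguments
#'   (`n`, `ratio`, `counts`, `distance`, `sigma`, `shape`, ...).
#' @param gravity_mode `"MICROGRAVITY"`, `"ONE_G"` or `"RWV"`.
#' @param rpm,r_B RWV rotation rate (rev/min) and arm (m).
#' @param diffusivity `"biofilm"`, `"intermediate"`, `"liquid"`, or m^2/s.
#' @param beta solutal expansion coefficient per (cell equivalent/um^3).
#' @param kickstart_product cell equivalents of own product per cell.
#' @param duration simulated time, s.
#' @param seed RNG seed (placements and species interleaving).
#' @param dt_fluid,dt_chem time steps, s (`dt_chem` must be an integer
#'   multiple of `dt_fluid`; growth is updated every chemical step).
#' @param cadence recording interval, s.
#' @param colony_mode `"INDIVIDUAL"` or `"RIGID_COLONY"` cell motion.
#' @param init_lactose initial uniform lactose concentration, ce/um^3.
#' @param lambda_E,lambda_S product-yield scalings (1 = baseline).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom",
                            placement = list(recipe = "two_cells", distance = 1),
                            gravity_mode = "MICROGRAVITY",
                            rpm = 10, r_B = 0.01,
                            diffusivity = "intermediate",
                            beta = .BETA_DEFAULT,
                            kickstart_product = 1e-5,
                            duration = 300,
                            seed = 1L,
                            dt_fluid = 0.1, dt_chem = 0.1,
                            cadence = 1,
                            colony_mode = "INDIVIDUAL",
                            init_lactose = 1e-3,
                            lambda_E = 1, lambda_S = 1) {
  stopifnot(duration > 0, dt_chem > 0, dt_fluid > 0,
            dt_chem + 1e-12 >= dt_fluid, cadence >= dt_chem)
  structure(as.list(environment()), class = "scenario_config")
}

#' Build the initial simulation state for a scenario
#'
#' Seeds the RNG, generates the placement, applies the kickstart, and
#' assembles fields, flow, and environment.
#'
#' @param config a [scenario_config()].
#' @return a `sim_state` list (cells, fields, env, params, metabolites,
#'   grid, time, ledger, series).
#' @export
build_state <- function(config) {
  set.seed(config$seed)
  grid <- grid_spec()
  params <- default_species(config$lambda_E, config$lambda_S)
  metabolites <- default_metabolites(
    config$diffusivity, beta = config$beta,
    S_ref = c(lactose = config$init_lactose, methionine = 0, acetate = 0))
  env <- sim_environment(config$gravity_mode, rpm = config$rpm,
                         r_B = config$r_B)
  pl <- config$placement
  placed <- switch(pl$recipe,
    dense_sphere = place_dense_sphere(pl$n, pl$ratio %||% c(1.86, 1),
                                      pl$center %||% NULL, grid, params),
    gaussian_sphere = place_gaussian_sphere(pl$n, pl$ratio %||% c(1.86, 1),
                                            pl$center %||% NULL,
                                            pl$sigma %||% NULL, grid, params),
    random_uniform = place_random_uniform(pl$n, pl$ratio %||% c(1.86, 1),
                                          grid, params),
    two_cells = place_two_cells(pl$distance, grid),
    separated_colonies = place_separated_colonies(pl$n1, pl$n2,
                                                  pl$distance %||% NULL,
                                                  pl$sigma %||% NULL,
                                                  grid, params),
    floor_biofilm = place_floor_biofilm(pl$shape %||% "SPHERE", pl$n,
                                        pl$ratio %||% c(1.86, 1),
                                        grid, params),
    stop(sprintf("build_state: unknown placement recipe '%s'", pl$recipe))
  )
  if (!is.null(pl$counts)) {
    ## explicit per-species counts (e.g. 1956:44): reassign labels
    counts <- pl$counts
    placed$species <- .species_labels(
      stats::setNames(as.integer(counts), c("ECOLI", "SENTERICA")))
  }
  cells <- new_cells(placed$species, placed$position, params)
  cells <- kickstart(cells, config$kickstart_product)
  fields <- field_set(grid, metabolites,
                      init_conc = c(lactose = config$init_lactose))
  fields$eps <- compute_void_fraction(cells, grid, params)
  fields$flow <- init_solid_body_rotation(fields$flow, env)
  ledger <- list(
    produced = c(lactose = 0, methionine = 0, acetate = 0),
    consumed = c(lactose = 0, methionine = 0, acetate = 0),
    outflow = c(lactose = 0, methionine = 0, acetate = 0),
    wall_events = 0
  )
  state <- list(cells = cells, fields = fields, env = env, params = params,
                metabolites = metabolites, grid = grid, config = config,
                time = 0, ledger = ledger, series = list(),
                placement = placed)
  state$total0 <- metabolite_totals(state)
  class(state) <- "sim_state"
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total cell equivalents of each metabolite (fields + cell pools)
#'
#' @param state a `sim_state`.
#' @return named numeric (lactose, methionine, acetate).
#' @export
metabolite_totals <- function(state) {
  grid <- state$grid
  tot <- vapply(names(state$fields$conc), function(nm) {
    sum(state$fields$conc[[nm]]) * grid$V_parcel_um3
  }, numeric(1))
  pro <- .sp_field(state$params, state$cells$species, "product", chr = TRUE)
  sub <- .sp_field(state$params, state$cells$species, "limiting_substrate",
                   chr = TRUE)
  for (nm in names(tot)) {
    tot[nm] <- tot[nm] + sum(state$cells$pool_pro[pro == nm]) +
      sum(state$cells$pool_sub[sub == nm])
  }
  tot
}

#' Global conservation audit
#'
#' Checks, per metabolite, that the change in total inventory (extracellular
#' plus intracellular) equals net biological production minus consumption
#' minus the advective outlet flux.
#'
#' @param state a `sim_state`.
#' @return list with per-metabolite residuals and `max_relative` (residual
#'   over the inventory scale).
#' @export
mass_audit <- function(state) {
  tot <- metabolite_totals(state)
  led <- state$ledger
  expected <- state$total0 + led$produced - led$consumed - led$outflow
  resid <- tot - expected
  scale <- pmax(abs(state$total0) + led$produced + led$consumed, 1e-12)
  list(residual = resid, relative = resid / scale,
       max_relative = max(abs(resid / scale)))
}

## apply the per-cell kinetics to parcels, pools, and masses over dt
.apply_biology <- function(state, kin, dt) {
  cells <- state$cells
  grid <- state$grid
  ## parcel inventory volume: the full parcel volume (the solid loading is
  ## well below 1% of the domain; the void fraction acts on the Sherwood
  ## correlation, not on storage)
  Vfl <- rep(grid$V_parcel_um3, prod(grid$n))
  n <- nrow(cells)
  Y_pro <- .sp_field(state$params, cells$species, "yield_product")
  pro <- .sp_field(state$params, cells$species, "product", chr = TRUE)
  ## --- substrate draws (zero-order conversion), guarded per parcel ------
  ## The conversion at k = mu_max is the cell's catabolic throughput of the
  ## limiting substrate; biomass accrual is bookkeeping on top of it (no
  ## second draw), so the cross-feeding yields alone set the community's
  ## metabolite budget.
  conv <- kin$conv_rate * dt
  phi <- rep(1, n)
  for (nm in unique(kin$sub)) {
    sel <- which(kin$sub == nm)
    tot_draw <- rowsum(conv[sel], kin$parcel_lin[sel])
    idx <- as.integer(rownames(tot_draw))
    avail <- 0.9 * state$fields$conc[[nm]][idx] * Vfl[idx]
    fac <- pmin(1, avail / pmax(tot_draw[, 1], 1e-300))
    phi[sel] <- fac[match(kin$parcel_lin[sel], idx)]
  }
  ## --- lactose co-substrate guard (E. coli conversion only) -------------
  has_co <- !is.na(kin$co)
  if (any(has_co)) {
    for (nm in unique(kin$co[has_co])) {
      sel <- which(has_co & kin$co == nm)
      need <- phi[sel] * conv[sel]
      tot_need <- rowsum(need, kin$parcel_lin[sel])
      idx <- as.integer(rownames(tot_need))
      avail <- 0.9 * state$fields$conc[[nm]][idx] * Vfl[idx]
      facL <- pmin(1, avail / pmax(tot_need[, 1], 1e-300))
      facL <- facL[match(kin$parcel_lin[sel], idx)]
      conv[sel] <- conv[sel] * facL   # conversion limited by lactose
    }
  }
  conv_eff <- phi * conv
  ## growth from the transmembrane difference actually achieved: the film
  ## flux equals the realized conversion rate, so dS scales with it
  dS_eff <- conv_eff / (kin$a_sub * dt)
  mu_eff <- growth_rate(dS_eff, 0, kin$mu_max, kin$K_S)
  dm <- cells$mass * (exp(mu_eff * dt) - 1)
  ## subtract conversion draws from the substrate fields
  for (nm in unique(kin$sub)) {
    sel <- which(kin$sub == nm)
    d <- rowsum(conv_eff[sel], kin$parcel_lin[sel])
    idx <- as.integer(rownames(d))
    state$fields$conc[[nm]][idx] <- pmax(
      state$fields$conc[[nm]][idx] - d[, 1] / Vfl[idx], 0)
    state$ledger$consumed[nm] <- state$ledger$consumed[nm] +
      sum(conv_eff[sel])
  }
  ## lactose consumption (1:1 with conversion where required)
  if (any(has_co)) {
    for (nm in unique(kin$co[has_co])) {
      sel <- which(has_co & kin$co == nm)
      d <- rowsum(conv_eff[sel], kin$parcel_lin[sel])
      idx <- as.integer(rownames(d))
      state$fields$conc[[nm]][idx] <- pmax(
        state$fields$conc[[nm]][idx] - d[, 1] / Vfl[idx], 0)
      state$ledger$consumed[nm] <- state$ledger$consumed[nm] + sum(conv_eff[sel])
    }
  }
  ## product formation into the intracellular pool
  cells$pool_pro <- cells$pool_pro + Y_pro * conv_eff
  for (nm in unique(pro)) {
    state$ledger$produced[nm] <- state$ledger$produced[nm] +
      sum(Y_pro[pro == nm] * conv_eff[pro == nm])
  }
  ## growth
  cells$mass <- cells$mass + dm
  cells$mu <- mu_eff
  state$cells <- cells
  state$kin_last <- kin
  state
}

#' Advance the simulation one chemical step
#'
#' @param state a `sim_state`.
#' @param dt chemical step, s.
#' @param n_fluid_sub fluid sub-steps within this step.
#' @return updated state.
#' @export
step_state <- function(state, dt, n_fluid_sub = 1L) {
  env <- state$env
  ## 1. fluid
  dtf <- dt / n_fluid_sub
  for (i in seq_len(n_fluid_sub)) {
    state$fields$flow <- step_fluid(state$fields$flow, state$fields, env,
                                    dtf, state$metabolites,
                                    t = state$time + (i - 1) * dtf)
  }
  ## 2. particle motion + void fraction (content-preserving rescale)
  if (nrow(state$cells) > 0L) {
    state$cells <- integrate_cells(state$cells, state$fields, env, dt,
                                   mode = state$config$colony_mode,
                                   t = state$time)
    state$ledger$wall_events <- state$ledger$wall_events +
      (attr(state$cells, "wall_events") %||% 0)
    state$fields$eps <- compute_void_fraction(state$cells, state$grid,
                                              state$params)
    ## 3. per-cell kinetics and parcel exchange
    kin <- cell_kinetics(state$cells, state$fields, env, state$params,
                         state$metabolites)
    state <- .apply_biology(state, kin, dt)
    ## 4. product film release
    ex <- exchange_with_cells(state$cells, state$fields, env, state$params,
                              state$metabolites, dt, pool = "product")
    state$cells <- ex$cells
    state$fields <- ex$fields
  }
  ## 5. scalar transport
  flow <- state$fields$flow
  for (nm in names(state$fields$conc)) {
    S <- step_scalar(state$fields$conc[[nm]], flow,
                     state$metabolites[[nm]]$D_M, dt, state$grid)
    state$ledger$outflow[nm] <- state$ledger$outflow[nm] +
      attr(S, "outflow_ce")
    attr(S, "outflow_ce") <- NULL
    state$fields$conc[[nm]] <- S
  }
  state$time <- state$time + dt
  state
}

## record one row of per-species statistics
.record_row <- function(state) {
  cells <- state$cells
  mu <- cells$mu %||% rep(0, nrow(cells))
  if (is.null(cells$mu)) cells$mu <- mu
  rows <- lapply(unique(cells$species), function(spn) {
    sel <- cells$species == spn
    qm <- stats::quantile(cells$mass[sel], c(0.25, 0.75), names = FALSE)
    qu <- stats::quantile(cells$mu[sel], c(0.25, 0.75), names = FALSE)
    data.frame(
      time = state$time, species = spn, n = sum(sel),
      mu_mean = mean(cells$mu[sel]),
      mu_q25 = qu[1], mu_q75 = qu[2],
      mass_mean = mean(cells$mass[sel]),
      mass_q25 = qm[1], mass_q75 = qm[2],
      mass_total = sum(cells$mass[sel]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run a scenario to completion
#'
#' Builds the state from the configuration and advances it for the
#' configured duration, recording per-species statistics at the recording
#' cadence and auditing conservation.
#'
#' @param config a [scenario_config()].
#' @param progress print a progress line every simulated minute.
#' @return a `sim_result` list: `config`, `series` (data.frame), `state`
#'   (final), `audit`, `steady` (per-species steady-state detection),
#'   `wall_events`.
#' @export
simulate_scenario <- function(config, progress = FALSE) {
  state <- build_state(config)
  dt <- config$dt_chem
  n_fluid_sub <- max(1L, as.integer(round(config$dt_chem / config$dt_fluid)))
  n_steps <- as.integer(round(config$duration / dt))
  rec_every <- max(1L, as.integer(round(config$cadence / dt)))
  series <- vector("list", n_steps %/% rec_every + 1L)
  state$cells$mu <- 0
  series[[1]] <- .record_row(state)
  ri <- 1L
  for (s in seq_len(n_steps)) {
    state <- step_state(state, dt, n_fluid_sub)
    if (s %% rec_every == 0L) {
      ri <- ri + 1L
      series[[ri]] <- .record_row(state)
    }
    if (progress && (s * dt) %% 60 == 0) {
      message(sprintf("  t = %.0f s", s * dt))
    }
  }
  series <- do.call(rbind, series[seq_len(ri)])
  steady <- lapply(split(series, series$species), function(d) {
    detect_steady_state(d$mu_mean, d$time)
  })
  res <- list(config = config, series = series, state = state,
              audit = mass_audit(state), steady = steady,
              wall_events = state$ledger$wall_events)
  class(res) <- "sim_result"
  res
}

#' Steady-state detection on a growth-rate series
#'
#' Growth is steady when the population-mean specific growth rate changes
#' by less than `tol` (relative) across the trailing `window` seconds.
#'
#' @param mu vector of population-mean growth rates.
#' @param time matching time vector, s.
#' @param window trailing window, s.
#' @param tol relative tolerance.
#' @return list `steady` (logical) and `mu_bar` (trailing-window mean).
#' @export
detect_steady_state <- function(mu, time, window = 30, tol = 0.01) {
  if (length(mu) < 2L || (max(time) - min(time)) <= window) {
    return(list(steady = FALSE, mu_bar = mean(mu)))
  }
  sel <- time >= max(time) - window
  m <- mu[sel]
  mu_bar <- mean(m)
  span <- max(m) - min(m)
  steady <- is.finite(mu_bar) && mu_bar > 0 && span / abs(mu_bar) < tol
  list(steady = steady, mu_bar = mu_bar)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result '%s'> %s, %.0f s simulated, %d cells\n",
              x$config$name, x$config$gravity_mode,
              max(x$series$time), nrow(x$state$cells)))
  for (spn in names(x$steady)) {
    st <- x$steady[[spn]]
    cat(sprintf("  %-10s mu_bar = %.3g 1/s (%s)\n", spn, st$mu_bar,
                if (st$steady) "steady" else "not steady"))
  }
  cat(sprintf("  audit max relative residual: %.2e\n", x$audit$max_relative))
  invisible(x)
}
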