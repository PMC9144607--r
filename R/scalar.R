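## Advection-diffusion of the three metabolites on the parcel grid, the
## void-fraction field, and the film-law exchange between cells and their
## parcels.

#' Void-fraction field from the current cell positions
#'
#' `eps_p = 1 - sum(V_cell in p) / V_parcel`, floored at `eps_min`; a parcel
#' pushed to or below zero before flooring raises an overcrowding warning
#' with its index.
#'
#' @param cells a `cell_table`.
#' @param grid a [grid_spec()].
#' @param params species parameter list (for per-species cell volumes).
#' @param eps_min floor applied to the void fraction.
#' @return array of dim `grid$n`.
#' @export
compute_void_fraction <- function(cells, grid, params, eps_min = 0.4) {
  eps <- array(1, grid$n)
  if (nrow(cells) == 0L) return(eps)
  lin <- .lin_index(parcel_index(cbind(cells$x, cells$y, cells$z), grid),
                   grid$n)
  V <- vapply(params, function(p) p$V_cell, numeric(1))[cells$species]
  occ <- rowsum(unname(V), lin)
  idx <- as.integer(rownames(occ))
  val <- 1 - occ[, 1] / grid$V_parcel_um3
  if (any(val <= 0)) {
    warning(sprintf("compute_void_fraction: %d parcel(s) overcrowded (first: %d)",
                    sum(val <= 0), idx[which(val <= 0)[1]]))
  }
  eps[idx] <- pmax(val, eps_min)
  eps
}

#' Advance one metabolite field one transport step
#'
#' Conservative first-order upwind advection (explicit) with periodic x/z
#' boundaries, zero advective flux through the y = 0 wall and upwinded flux
#' through the outlet face, followed by an implicit (backward-Euler)
#' constant-coefficient diffusion solve with zero-normal-gradient conditions
#' at both radial walls.  The implicit solve preserves the field mean
#' exactly, so transport conserves mass up to the outlet flux, which is
#' returned for the global audit.
#'
#' @param S concentration array (cell equivalents/um^3).
#' @param flow a [flow_state()] (`NULL` for pure diffusion).
#' @param D_M diffusivity, m^2/s.
#' @param dt time step, s.
#' @param grid a [grid_spec()].
#' @param sources optional per-parcel net rate array (cell equiv/um^3/s).
#' @return updated array; attribute `outflow_ce` holds the cell equivalents
#'   advected out through the outlet this step (negative = gained).
#' @export
step_scalar <- function(S, flow, D_M, dt, grid, sources = NULL) {
  h <- grid$parcel_um
  n <- grid$n
  outflow <- 0
  if (!is.null(flow)) {
    umax <- max(abs(flow$u), abs(flow$v), abs(flow$w))
    if (umax > 0) {
      ## face velocities in um/s
      uf <- m_to_um(flow$u); vf <- m_to_um(flow$v); wf <- m_to_um(flow$w)
      upw <- function(vel, Sb, Sf) {
        pos <- vel > 0
        vel * (Sb * pos + Sf * !pos)
      }
      Fx <- upw(uf, .shiftp(S, 1L, -1L), S)                # flux at x-faces
      ny <- n[2]
      Fy <- array(0, dim(vf))
      Fy[, 2:ny, ] <- upw(vf[, 2:ny, , drop = FALSE],
                          S[, 1:(ny - 1), , drop = FALSE],
                          S[, 2:ny, , drop = FALSE])
      ## outlet face: upwind with zero-gradient exterior value
      Fy[, ny + 1L, ] <- vf[, ny + 1L, ] * S[, ny, ]
      Fz <- upw(wf, .shiftp(S, 3L, -1L), S)
      divF <- (.shiftp(Fx, 1L, 1L) - Fx) / h[1] +
        (Fy[, 2:(ny + 1), , drop = FALSE] -
           Fy[, 1:ny, , drop = FALSE]) / h[2] +
        (.shiftp(Fz, 3L, 1L) - Fz) / h[3]
      S <- S - dt * divF
      outflow <- sum(Fy[, ny + 1L, ]) * h[1] * h[3] * dt
    }
  }
  if (!is.null(sources)) S <- S + dt * sources
  rng <- range(S)
  if (rng[1] == rng[2]) {              # uniform field: diffusion is a no-op
    attr(S, "outflow_ce") <- outflow
    return(S)
  }
  ## implicit diffusion, D in um^2/s on the um grid
  D_um <- D_M * 1e12
  grid_um <- grid
  grid_um$parcel_m <- grid$parcel_um   # solve in um units
  S <- .helmholtz_solve(S, D_um * dt, grid_um, "neumann", "neumann")
  neg <- min(S)
  if (neg < -1e-9 * max(abs(S), 1e-300)) {
    stop(sprintf("step_scalar: negative concentration %.3g (conservation failure)",
                 neg))
  }
  S[S < 0] <- 0
  attr(S, "outflow_ce") <- outflow
  S
}

#' Film-law exchange between cell pools and their parcels
#'
#' Applies the film mass-transfer law `d(pool)/dt = A_C h_S (S_f - S_C)`
#' (with `S_C = pool / V_cell` the intracellular concentration) exactly over
#' the step, as the two-compartment linear relaxation between the cell and
#' the fluid fraction of its parcel.  Bidirectional: the pool takes up when
#' the parcel is richer and releases (secretes) when the pool is richer.
#' Conservative by construction.
#'
#' @param cells a `cell_table`.
#' @param fields a [field_set()].
#' @param env a [sim_environment()].
#' @param params species parameter list.
#' @param metabolites named list of [metabolite_spec()].
#' @param dt time step, s.
#' @param pool `"product"` (each cell's secreted metabolite, the default) or
#'   `"substrate"` (its limiting substrate).
#' @return list with the updated `cells`, updated `fields`, and `source_map`
#'   (named list of per-parcel deposited cell equivalents, one array per
#'   touched metabolite).
#' @export
exchange_with_cells <- function(cells, fields, env, params, metabolites, dt,
                                pool = c("product", "substrate")) {
  pool <- match.arg(pool)
  grid <- fields$grid
  if (nrow(cells) == 0L) return(list(cells = cells, fields = fields,
                                     source_map = list()))
  kin <- cell_transfer_coefficients(cells, fields, env, params, metabolites)
  met_name <- .sp_field(params, cells$species,
                        if (pool == "product") "product"
                        else "limiting_substrate", chr = TRUE)
  V_c <- .sp_field(params, cells$species, "V_cell")
  A_c <- 4 * pi * cells$r_um^2
  pool_col <- if (pool == "product") "pool_pro" else "pool_sub"
  amt <- cells[[pool_col]]
  source_map <- list()
  for (nm in unique(met_name)) {
    sel <- which(met_name == nm)
    lin <- kin$parcel_lin[sel]
    hm <- m_to_um(kin$h[sel, nm])               # um/s
    a <- A_c[sel] * hm                          # um^3/s
    Vfluid <- rep(grid$V_parcel_um3, length(lin))
    Cf <- fields$conc[[nm]][lin]                # parcel concentration
    content <- Cf * Vfluid
    Vc <- V_c[sel]
    total <- amt[sel] + content
    Ceq <- total / (Vc + Vfluid)
    kap <- a * (1 / Vc + 1 / Vfluid)
    decay <- exp(-kap * dt)
    new_pool <- Ceq * Vc + (amt[sel] - Ceq * Vc) * decay
    dep <- amt[sel] - new_pool                  # into the parcel
    dep_parcel <- rowsum(dep, lin)
    idx <- as.integer(rownames(dep_parcel))
    smap <- array(0, grid$n)
    smap[idx] <- dep_parcel[, 1]
    ## parcels never driven negative: uptake is bounded by the exact
    ## relaxation, but several cells sharing a parcel are applied against
    ## the same start-of-step value; clamp and return the residue to pools
    avail <- fields$conc[[nm]][idx] * grid$V_parcel_um3
    short <- pmax(-smap[idx] - avail, 0)
    if (any(short > 0)) {
      fac <- ifelse(smap[idx] < 0, avail / pmax(-smap[idx], 1e-300), 1)
      fac <- pmin(fac, 1)
      scl <- fac[match(lin, idx)]
      dep <- ifelse(dep < 0, dep * scl, dep)
      new_pool <- amt[sel] - dep
      dep_parcel <- rowsum(dep, lin)
      smap[idx] <- dep_parcel[, 1]
    }
    amt[sel] <- new_pool
    fields$conc[[nm]][idx] <- fields$conc[[nm]][idx] +
      smap[idx] / grid$V_parcel_um3
    source_map[[nm]] <- smap
  }
  cells[[pool_col]] <- amt
  list(cells = cells, fields = fields, source_map = source_map)
}
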