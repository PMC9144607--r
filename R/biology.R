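## Per-cell kinetics: Sherwood-correlation mass-transfer coefficients,
## zero-order cross-feeding conversion, and mass-transfer-limited Monod
## growth.
##
## The film-exchange relaxation time V_cell / (A_C h_S) is ~1e-4 s, orders
## of magnitude below the chemical step, so the intracellular substrate
## concentration is advanced to its quasi-steady balance each step: the
## transmembrane difference is the one that lets the film flux carry the
## cell's consumption, `dS = consumption / (A_C h_S)`, capped at the parcel
## concentration (empty-cell limit).  The growth law is Monod in that
## transmembrane difference.

## fast per-cell lookup of a species parameter: one vapply over the (two)
## species, then a named-vector index
.sp_field <- function(params, species, field, chr = FALSE) {
  tab <- if (chr) {
    vapply(params, function(p) as.character(p[[field]]), character(1))
  } else {
    vapply(params, function(p) p[[field]], numeric(1))
  }
  unname(tab[species])
}

#' Sherwood number for a particle in a fluid parcel
#'
#' Empirical correlation for dense particulate flows,
#' `Sh = (7 - 10 e + 5 e^2)(1 + 0.17 Re^(1/5) Sc^(1/3))
#'       + (1.33 - 2.31 e + 1.16 e^2) Re^(7/10) Sc^(1/3)`,
#' valid for `0 <= Re_P <= 100`.  At `Re_P = 0` it reduces to
#' `7 - 10 e + 5 e^2` (the quiescent-sphere value 2 at e = 1).
#'
#' @param eps fluid volume fraction(s), in (0, 1].
#' @param Re_P particle Reynolds number(s); values above 100 are clamped
#'   with a warning (the flows simulated here are creeping).
#' @param Sc Schmidt number(s).
#' @return Sherwood number(s).
#' @export
sherwood <- function(eps, Re_P, Sc) {
  if (any(eps <= 0 | eps > 1)) stop("sherwood: eps must be in (0, 1]")
  if (any(Re_P < 0)) stop("sherwood: Re_P must be >= 0")
  if (any(Re_P > 100)) {
    warning("sherwood: Re_P > 100 clamped to the correlation range")
    Re_P <- pmin(Re_P, 100)
  }
  e2 <- eps^2
  (7 - 10 * eps + 5 * e2) * (1 + 0.17 * Re_P^(1 / 5) * Sc^(1 / 3)) +
    (1.33 - 2.31 * eps + 1.16 * e2) * Re_P^(7 / 10) * Sc^(1 / 3)
}

#' Mass-transfer coefficient from the Sherwood number
#'
#' `h_S = Sh * D_M / (2 r)`.
#'
#' @param Sh Sherwood number(s).
#' @param D_M diffusivity, m^2/s.
#' @param radius particle radius, m.
#' @return h_S in m/s.
#' @export
mass_transfer_coefficient <- function(Sh, D_M, radius) {
  if (any(D_M <= 0) || any(radius <= 0) || any(Sh <= 0)) {
    stop("mass_transfer_coefficient: arguments must be positive")
  }
  Sh * D_M / (2 * radius)
}

#' Monod half-saturation constant from the mass-transfer coefficient
#'
#' `K_S = rho_c d_c mu_max / (6 Y_XS h_S)`: the half-saturation of the
#' mass-transfer-limited Monod law is inversely proportional to h_S, with
#' the biomass density expressed in cell equivalents (`rho_c = 1/V_cell`).
#'
#' @param h_S mass-transfer coefficient, m/s.
#' @param species a [species_params()].
#' @return K_S in cell equivalents/um^3.
#' @export
monod_Ks <- function(h_S, species) {
  if (any(h_S <= 0)) stop("monod_Ks: h_S must be > 0")
  species$rho_c_ce * species$d_c_um * species$mu_max /
    (6 * species$Y_XS * m_to_um(h_S))
}

#' Mass-transfer-limited Monod growth rate
#'
#' `mu = mu_max (S_f - S_C) / (K_S + (S_f - S_C))` for `S_f > S_C`, else 0
#' (anabolic growth only; no shrinkage under a reversed gradient).
#'
#' @param S_f,S_C extracellular (parcel) and intracellular concentrations,
#'   cell equivalents/um^3.
#' @param mu_max maximum specific growth rate, 1/s.
#' @param K_S half-saturation constant, cell equivalents/um^3.
#' @return specific growth rate, 1/s.
#' @export
growth_rate <- function(S_f, S_C, mu_max, K_S) {
  dS <- pmax(S_f - S_C, 0)
  mu_max * dS / (K_S + dS)
}

#' Zero-order cross-feeding conversion of intracellular pools
#'
#' Converts up to `k dt mass` cell equivalents of limiting substrate from
#' the `pool_sub` pool into `yield_product` times that amount of product in
#' `pool_pro`; for E. coli an equal amount of lactose co-substrate is
#' required and drawn from `lactose_available`.
#'
#' @param cells a `cell_table`.
#' @param params species parameter list.
#' @param dt time step, s.
#' @param lactose_available per-cell lactose available for conversion,
#'   cell equivalents (default unlimited).
#' @return `cells` with updated pools; attributes `converted` and
#'   `produced` give per-cell amounts.
#' @export
convert_substrate <- function(cells, params, dt, lactose_available = Inf) {
  if (dt <= 0) stop("convert_substrate: dt must be > 0")
  k <- .sp_field(params, cells$species, "k_convert")
  Y <- .sp_field(params, cells$species, "yield_product")
  needs_co <- !is.na(.sp_field(params, cells$species, "co_substrate",
                               chr = TRUE))
  amount <- pmin(k * cells$mass * dt, cells$pool_sub)
  amount <- ifelse(needs_co, pmin(amount, lactose_available), amount)
  amount <- pmax(amount, 0)
  cells$pool_sub <- cells$pool_sub - amount
  cells$pool_pro <- cells$pool_pro + Y * amount
  attr(cells, "converted") <- amount
  attr(cells, "produced") <- Y * amount
  cells
}

#' Exponential biomass update
#'
#' `mass <- mass exp(mu dt)`; anabolic growth only, no division, no decay.
#'
#' @param mass biomass, cell equivalents.
#' @param mu specific growth rate(s), 1/s (must be >= 0).
#' @param dt time step, s.
#' @return updated mass.
#' @export
update_mass <- function(mass, mu, dt) {
  if (any(mu < 0)) stop("update_mass: mu must be >= 0")
  mass * exp(mu * dt)
}

#' Per-cell transfer coefficients from the local flow state
#'
#' Computes, for every cell and metabolite, the particle Reynolds number
#' from the quasi-steady slip velocity, the Schmidt number, the Sherwood
#' number at the local void fraction, and the film coefficient h_S.
#'
#' @param cells a `cell_table`.
#' @param fields a [field_set()].
#' @param env a [sim_environment()].
#' @param params species parameter list.
#' @param metabolites named list of [metabolite_spec()].
#' @return list with `h` (n x metabolites matrix, m/s), `Sh` (same shape),
#'   `Re_P`, `Sc` (named), `eps_local`, `parcel_lin`, `u_f`, `S_f`.
#' @export
cell_transfer_coefficients <- function(cells, fields, env, params,
                                       metabolites) {
  pos <- cbind(cells$x, cells$y, cells$z)
  samp <- interp_fluid_to_cell(fields, pos)
  v_s <- cbind(cells$vx, cells$vy, cells$vz)
  slip <- sqrt(rowSums((v_s - samp$u_f)^2))
  r_m <- um_to_m(cells$r_um)
  Re_P <- slip * 2 * r_m / env$nu
  Sc <- vapply(metabolites, function(m) env$nu / m$D_M, numeric(1))
  h <- matrix(0, nrow(cells), length(metabolites),
              dimnames = list(NULL, names(metabolites)))
  Sh_m <- h
  for (j in seq_along(metabolites)) {
    Shj <- sherwood(samp$eps_local, Re_P, Sc[j])
    Sh_m[, j] <- Shj
    h[, j] <- mass_transfer_coefficient(Shj, metabolites[[j]]$D_M, r_m)
  }
  list(h = h, Sh = Sh_m, Re_P = Re_P, Sc = Sc, eps_local = samp$eps_local,
       parcel_lin = samp$parcel_lin, u_f = samp$u_f, S_f = samp$S_f)
}

#' Quasi-steady per-cell kinetic state
#'
#' Solves the per-cell film balance: the zero-order conversion demand
#' `k mass` (for E. coli additionally capped by the lactose the film can
#' deliver) sets the transmembrane concentration difference
#' `dS = conversion / (A_C h_S)`, capped at the parcel concentration when
#' the demand exceeds what the film can deliver (the cell then runs
#' supply-limited at `A_C h_S S_f`).  The growth rate is the Monod law in
#' `dS` with the half-saturation from [monod_Ks()].
#'
#' @inheritParams cell_transfer_coefficients
#' @return data.frame, one row per cell: `mu` (1/s), `K_S`, `dS`, `h_sub`
#'   (m/s), `Re_P`, `conv_rate` (cell equiv/s), `supply_limited`,
#'   `parcel_lin`, plus the per-metabolite coefficient matrix as attribute
#'   `h`.
#' @export
cell_kinetics <- function(cells, fields, env, params, metabolites) {
  tc <- cell_transfer_coefficients(cells, fields, env, params, metabolites)
  k <- .sp_field(params, cells$species, "k_convert")
  mu_max <- .sp_field(params, cells$species, "mu_max")
  Y_XS <- .sp_field(params, cells$species, "Y_XS")
  sub <- .sp_field(params, cells$species, "limiting_substrate", chr = TRUE)
  co <- .sp_field(params, cells$species, "co_substrate", chr = TRUE)
  rho_c <- .sp_field(params, cells$species, "rho_c_ce")
  d_c <- .sp_field(params, cells$species, "d_c_um")
  A_c <- 4 * pi * cells$r_um^2                     # um^2
  n <- nrow(cells)
  cidx <- seq_len(n)
  h_sub <- tc$h[cbind(cidx, match(sub, colnames(tc$h)))]
  a_sub <- A_c * m_to_um(h_sub)                    # um^3/s
  S_f <- numeric(n)
  for (nm in unique(sub)) {
    sel <- sub == nm
    S_f[sel] <- tc$S_f[[nm]][sel]
  }
  ## conversion demand, capped by lactose film delivery where required
  demand <- k * cells$mass
  has_co <- !is.na(co)
  if (any(has_co)) {
    cap_co <- rep(Inf, n)
    for (nm in unique(co[has_co])) {
      sel <- !is.na(co) & co == nm
      h_co <- tc$h[cbind(cidx[sel], match(nm, colnames(tc$h)))]
      cap_co[sel] <- A_c[sel] * m_to_um(h_co) * tc$S_f[[nm]][sel]
    }
    demand <- pmin(demand, cap_co)
  }
  dS_req <- demand / a_sub
  supply_limited <- dS_req >= S_f
  dS <- pmin(dS_req, S_f)
  conv_rate <- ifelse(supply_limited, a_sub * S_f, demand)
  K_S <- rho_c * d_c * mu_max / (6 * Y_XS * m_to_um(h_sub))
  mu <- growth_rate(dS, 0, mu_max, K_S)
  out <- data.frame(
    mu = mu, K_S = K_S, dS = dS, h_sub = h_sub, Re_P = tc$Re_P,
    conv_rate = conv_rate, supply_limited = supply_limited,
    parcel_lin = tc$parcel_lin, a_sub = a_sub, S_f = S_f,
    mu_max = mu_max, Y_XS = Y_XS, sub = sub, co = co,
    stringsAsFactors = FALSE
  )
  attr(out, "h") <- tc$h
  attr(out, "eps_local") <- tc$eps_local
  out
}
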