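## Interpolation between the parcel grid and Lagrangian cell positions.
## Lateral axes (x, z) are periodic; the radial axis (y) uses a clamped
## one-sided stencil at the walls.

#' Parcel index containing each position
#'
#' @param pos n x 3 matrix of positions, um.
#' @param grid a [grid_spec()].
#' @return n x 3 integer matrix of parcel indices (1-based).
#' @export
parcel_index <- function(pos, grid) {
  idx <- sapply(1:3, function(a) {
    i <- floor(pos[, a] / grid$parcel_um[a]) + 1L
    if (a %in% c(1L, 3L)) {
      ((as.integer(i) - 1L) %% grid$n[a]) + 1L
    } else {
      pmin(pmax(as.integer(i), 1L), grid$n[a])
    }
  })
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  idx
}

## linear index into an (nx, ny, nz) array from an n x 3 index matrix
.lin_index <- function(ijk, n) {
  (ijk[, 3] - 1L) * (n[1] * n[2]) + (ijk[, 2] - 1L) * n[1] + ijk[, 1]
}

#' Trilinear interpolation of a parcel field to arbitrary positions
#'
#' Values live at parcel centers.  Periodic wrap on x and z; clamped
#' (one-sided) stencil at the radial walls, so the interpolant is exact for
#' fields linear in x and z everywhere and linear in y away from the wall
#' half-parcels.
#'
#' @param field array of dim `grid$n`.
#' @param pos n x 3 matrix of positions, um.
#' @param grid a [grid_spec()].
#' @return numeric vector of interpolated values.
#' @export
interp_field <- function(field, pos, grid) {
  n <- grid$n
  h <- grid$parcel_um
  ## fractional coordinate relative to parcel centers
  g <- lapply(1:3, function(a) pos[, a] / h[a] - 0.5)
  i0 <- lapply(g, floor)
  fr <- lapply(1:3, function(a) g[[a]] - i0[[a]])
  wrap <- function(i, a) {
    if (a %in% c(1L, 3L)) ((as.integer(i)) %% n[a]) + 1L
    else pmin(pmax(as.integer(i) + 1L, 1L), n[a])
  }
  ix0 <- wrap(i0[[1]], 1L); ix1 <- wrap(i0[[1]] + 1, 1L)
  iy0 <- wrap(i0[[2]], 2L); iy1 <- wrap(i0[[2]] + 1, 2L)
  iz0 <- wrap(i0[[3]], 3L); iz1 <- wrap(i0[[3]] + 1, 3L)
  fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
  gv <- function(ix, iy, iz) field[.lin_index(cbind(ix, iy, iz), n)]
  out <-
    gv(ix0, iy0, iz0) * (1 - fx) * (1 - fy) * (1 - fz) +
    gv(ix1, iy0, iz0) * fx       * (1 - fy) * (1 - fz) +
    gv(ix0, iy1, iz0) * (1 - fx) * fy       * (1 - fz) +
    gv(ix1, iy1, iz0) * fx       * fy       * (1 - fz) +
    gv(ix0, iy0, iz1) * (1 - fx) * (1 - fy) * fz +
    gv(ix1, iy0, iz1) * fx       * (1 - fy) * fz +
    gv(ix0, iy1, iz1) * (1 - fx) * fy       * fz +
    gv(ix1, iy1, iz1) * fx       * fy       * fz
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out))[1]
    stop(sprintf("interp_field: non-finite field value near parcel (%d,%d,%d)",
                 ix0[bad], iy0[bad], iz0[bad]))
  }
  out
}

#' Sample the fluid state at cell positions
#'
#' Returns the body-frame fluid velocity (trilinear from the cell-centered
#' average of the staggered grid), the per-metabolite parcel concentration
#' (value of the parcel containing the cell, the compartment the cell
#' exchanges with), and the local void fraction.
#'
#' @param fields a [field_set()].
#' @param pos n x 3 matrix of positions, um.
#' @return list with `u_f` (n x 3, m/s), `S_f` (named list of numeric
#'   vectors), `eps_local` (numeric vector), `parcel` (n x 3 indices).
#' @export
interp_fluid_to_cell <- function(fields, pos) {
  grid <- fields$grid
  idx <- parcel_index(pos, grid)
  lin <- .lin_index(idx, grid$n)
  flow <- fields$flow
  umax <- attr(flow, "umax") %||%
    max(abs(flow$u), abs(flow$v), abs(flow$w))
  u_f <- if (umax == 0) {
    matrix(0, nrow(pos), 3)
  } else {
    uc <- flow_center_velocity(flow)
    cbind(
      interp_field(uc$u, pos, grid),
      interp_field(uc$v, pos, grid),
      interp_field(uc$w, pos, grid)
    )
  }
  S_f <- lapply(fields$conc, function(a) a[lin])
  list(u_f = u_f, S_f = S_f, eps_local = fields$eps[lin], parcel = idx,
       parcel_lin = lin)
}
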