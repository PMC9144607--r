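## Lagrangian cell motion: Stokes drag, centrifugal, Coriolis, and
## gravity-buoyancy accelerations in the rotating body frame.
##
## The Stokes velocity relaxation time (rho_s/rho_f weighted, ~1e-7 s for a
## half-micron cell) is far below any usable time step, so integration is
## overdamped: each step sets the velocity to the quasi-steady (terminal)
## solution of the body-frame force balance, a 3x3 linear solve that retains
## the Coriolis coupling, then advances positions.

#' Stokes drag force on a sphere
#'
#' `F = -6 pi r mu (v_s - u_f)`, valid at vanishing particle Reynolds number.
#'
#' @param radius sphere radius, m (scalar or length-n).
#' @param mu_dyn dynamic viscosity, Pa s.
#' @param v_s,u_f particle and fluid velocities, n x 3 matrices (m/s).
#' @return n x 3 matrix of forces, N.
#' @export
stokes_drag_force <- function(radius, mu_dyn, v_s, u_f) {
  if (any(radius <= 0)) stop("stokes_drag_force: radius must be > 0")
  if (mu_dyn <= 0) stop("stokes_drag_force: mu_dyn must be > 0")
  v_s <- rbind(v_s); u_f <- rbind(u_f)
  -6 * pi * radius * mu_dyn * (v_s - u_f)
}

## drag rate coefficient c = (9/2) (rho_f/rho_s) nu / r^2  [1/s]
.drag_rate <- function(env, r_m) {
  4.5 * (env$rho_f / env$rho_s) * env$nu / r_m^2
}

#' Body-frame acceleration decomposition for cells
#'
#' Net body-frame acceleration
#' `a_B = -omega x (omega x r_B) (1 - rho_f/rho_s) - 2 omega x v_B
#'        + g_body(t) (1 - rho_f/rho_s) - (9/2)(rho_f/rho_s) nu (v_s - u_f)/r^2`,
#' with the centrifugal term applied as a uniform body force along the radial
#' axis.  Archimedean buoyancy enters the centrifugal and gravity terms
#' through the specific-gravity factor.
#'
#' @param cells a `cell_table` (uses velocity columns and `r_um`).
#' @param env a [sim_environment()].
#' @param u_f n x 3 fluid velocity at the cells, m/s.
#' @param t simulated time, s (sets the RWV body-frame gravity direction).
#' @return list of n x 3 matrices: `a_centrifugal`, `a_coriolis`,
#'   `a_gravity`, `a_drag`, `a_total` (m/s^2).
#' @export
body_frame_acceleration <- function(cells, env, u_f, t = 0) {
  n <- nrow(cells)
  if (any(cells$r_um <= 0)) stop("body_frame_acceleration: zero cell radius")
  buoy <- 1 - env$rho_f / env$rho_s
  one <- matrix(1, n, 1)
  a_cent <- one %*% (centrifugal_accel(env) * buoy)
  a_grav <- one %*% (gravity_body(env, t) * buoy)
  vB <- cbind(cells$vx, cells$vy, cells$vz)
  ## omega along z: -2 omega x v = (2 w vy, -2 w vx, 0)
  a_cor <- cbind(2 * env$omega * vB[, 2], -2 * env$omega * vB[, 1], 0 * vB[, 3])
  c_drag <- .drag_rate(env, um_to_m(cells$r_um))
  a_drag <- -c_drag * (vB - u_f)
  list(a_centrifugal = a_cent, a_coriolis = a_cor, a_gravity = a_grav,
       a_drag = a_drag, a_total = a_cent + a_cor + a_grav + a_drag)
}

#' Quasi-steady (terminal) body-frame velocity
#'
#' Solves `a_B = 0` for the velocity: `(c I + 2 Omega x) v = c u_f + a_ext`,
#' where `c` is the Stokes drag rate and `a_ext` the centrifugal plus
#' gravity-buoyancy acceleration.  With omega along z the 3x3 system has the
#' closed form used here.
#'
#' @param env a [sim_environment()].
#' @param u_f n x 3 fluid velocity, m/s.
#' @param a_ext n x 3 external (non-drag, non-Coriolis) acceleration, m/s^2.
#' @param r_m cell radii, m.
#' @return n x 3 terminal velocity, m/s.
#' @export
terminal_velocity <- function(env, u_f, a_ext, r_m) {
  cdr <- .drag_rate(env, r_m)
  b <- cdr * u_f + a_ext
  w2 <- 2 * env$omega
  den <- cdr^2 + w2^2
  cbind(
    (cdr * b[, 1] + w2 * b[, 2]) / den,
    (cdr * b[, 2] - w2 * b[, 1]) / den,
    b[, 3] / cdr
  )
}

#' Advance cell positions one step
#'
#' Velocities are set to the quasi-steady solution of the body-frame force
#' balance (including Coriolis) and positions advance by `v dt`.  Lateral
#' axes wrap periodically; cells reaching a radial wall are clamped there
#' with zero wall-normal velocity and the event is counted (attribute
#' `wall_events`), never silently lost.  In `RIGID_COLONY` mode all cells
#' share one velocity computed from the summed non-drag forces and summed
#' drag coefficients.
#'
#' @param cells a `cell_table`.
#' @param fields a [field_set()] (supplies the fluid velocity).
#' @param env a [sim_environment()].
#' @param dt time step, s.
#' @param mode `"INDIVIDUAL"`, `"RIGID_COLONY"`, or `"STATIC"`
#'   (wall-attached biofilm: cells do not move; the slip velocity seen by
#'   the mass-transfer correlation is then the local fluid velocity).
#' @param t simulated time at the start of the step, s.
#' @return updated `cell_table`; attribute `wall_events` holds the number of
#'   wall clamps applied this step.
#' @export
integrate_cells <- function(cells, fields, env, dt,
                            mode = c("INDIVIDUAL", "RIGID_COLONY", "STATIC"),
                            t = 0) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("integrate_cells: dt must be > 0")
  if (mode == "STATIC") {
    cells$vx <- 0; cells$vy <- 0; cells$vz <- 0
    attr(cells, "wall_events") <- 0L
    return(cells)
  }
  grid <- fields$grid
  pos <- cbind(cells$x, cells$y, cells$z)
  samp <- interp_fluid_to_cell(fields, pos)
  buoy <- 1 - env$rho_f / env$rho_s
  n <- nrow(cells)
  a_ext <- matrix(1, n, 1) %*%
    ((centrifugal_accel(env) + gravity_body(env, t)) * buoy)
  r_m <- um_to_m(cells$r_um)
  if (mode == "RIGID_COLONY" && n > 1) {
    ## shared velocity: force balance of the aggregate treated as N
    ## independent Stokes spheres (summed drag, summed body forces)
    cdr <- .drag_rate(env, r_m)
    m_rel <- cells$mass / sum(cells$mass)
    ## (C I + 2 Omega x) v = B with mass-weighted aggregates
    C <- sum(cdr * m_rel)
    B <- colSums((cdr * samp$u_f + a_ext) * m_rel)
    w2 <- 2 * env$omega
    den <- C^2 + w2^2
    v1 <- c((C * B[1] + w2 * B[2]) / den,
            (C * B[2] - w2 * B[1]) / den,
            B[3] / C)
    v <- matrix(v1, n, 3, byrow = TRUE)
  } else {
    v <- terminal_velocity(env, samp$u_f, a_ext, r_m)
  }
  pos <- pos + m_to_um(v) * dt
  ## periodic wrap on x, z
  pos[, 1] <- pos[, 1] %% grid$extent_um[1]
  pos[, 3] <- pos[, 3] %% grid$extent_um[3]
  ## clamp at radial walls, zero wall-normal velocity
  ylo <- cells$r_um
  yhi <- grid$extent_um[2] - cells$r_um
  hit <- pos[, 2] < ylo | pos[, 2] > yhi
  if (any(hit)) {
    pos[, 2] <- pmin(pmax(pos[, 2], ylo), yhi)
    v[hit, 2] <- 0
  }
  cells$x <- pos[, 1]; cells$y <- pos[, 2]; cells$z <- pos[, 3]
  cells$vx <- v[, 1]; cells$vy <- v[, 2]; cells$vz <- v[, 3]
  attr(cells, "wall_events") <- sum(hit)
  cells
}
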