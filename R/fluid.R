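## Incompressible flow on the parcel grid, in the rotating body frame, with
## solutal Boussinesq buoyancy.
##
## Discretization: staggered (MAC) finite volumes on the uniform parcel
## grid, first-order upwind advection, backward-Euler implicit viscosity,
## and a Chorin projection whose Poisson solve is exact (FFT in the periodic
## x/z axes, tridiagonal in y), so the discrete divergence after every step
## is at round-off.  Boundary conditions: periodic in x and z; the outer
## radial wall (y = 0) is a zero-velocity inlet (no-slip), the inner wall
## (y = Ly) a zero-normal-gradient freestream outlet with the modified
## pressure pinned to zero at the outlet face.  The flows of interest are
## creeping (cell Peclet ~ 0.05), which is why scheme simplicity is
## preferred over formal order.
##
## The momentum equation is solved with the fluid volume fraction set to 1
## (`ignore_eps_in_fluid`); the solid loading never exceeds a fraction of a
## percent of the domain, and the void fraction still acts on the Sherwood
## correlation and the parcel-volume bookkeeping.

#' Staggered-grid flow state
#'
#' @param grid a [grid_spec()].
#' @return list with face-velocity arrays `u` (x-faces, nx x ny x nz), `v`
#'   (y-faces, nx x (ny+1) x nz), `w` (z-faces), the modified pressure `p`
#'   (cell-centered, Pa/(kg/m^3) i.e. p_rgh/rho), and `div_residual`.
#' @export
flow_state <- function(grid) {
  n <- grid$n
  fl <- structure(list(
    u = array(0, n),
    v = array(0, c(n[1], n[2] + 1L, n[3])),
    w = array(0, n),
    p = array(0, n),
    div_residual = 0
  ), class = "flow_state")
  attr(fl, "umax") <- 0
  fl
}

#' Initialize the body-frame flow field
#'
#' Solid-body rotation in the RWV appears as rest in the co-rotating frame,
#' so all gravity modes start from an identically zero body-frame velocity.
#'
#' @param flow a [flow_state()].
#' @param env a [sim_environment()].
#' @return the flow state with zero velocity and pressure.
#' @export
init_solid_body_rotation <- function(flow, env) {
  flow$u[] <- 0; flow$v[] <- 0; flow$w[] <- 0; flow$p[] <- 0
  flow$div_residual <- 0
  attr(flow, "umax") <- 0
  flow
}

#' Cell-centered velocity from the staggered grid
#'
#' @param flow a [flow_state()].
#' @return list of three cell-centered arrays `u`, `v`, `w` (m/s).
#' @export
flow_center_velocity <- function(flow) {
  ny <- dim(flow$v)[2] - 1L
  list(
    u = (flow$u + .shiftp(flow$u, 1L, 1L)) / 2,
    v = (flow$v[, 1:ny, , drop = FALSE] +
           flow$v[, 2:(ny + 1), , drop = FALSE]) / 2,
    w = (flow$w + .shiftp(flow$w, 3L, 1L)) / 2
  )
}

#' Divergence of the face-velocity field
#'
#' @param flow a [flow_state()].
#' @param grid a [grid_spec()].
#' @return cell-centered array, 1/s.
#' @export
flow_divergence <- function(flow, grid) {
  h <- grid$parcel_m
  ny <- grid$n[2]
  (.shiftp(flow$u, 1L, 1L) - flow$u) / h[1] +
    (flow$v[, 2:(ny + 1), , drop = FALSE] -
       flow$v[, 1:ny, , drop = FALSE]) / h[2] +
    (.shiftp(flow$w, 3L, 1L) - flow$w) / h[3]
}

#' Solutal Boussinesq buoyancy acceleration field
#'
#' `(g_body(t) + a_c) * sum_i beta_i (S_i - S_i^ref)` per parcel: density
#' differences induced by the three metabolites act only through the
#' buoyancy term, once per metabolite.  Zero identically in microgravity
#' (g = 0, a_c = 0) whatever the gradients.
#'
#' By default the instantaneous domain-mean of the buoyancy factor is
#' subtracted: the domain is a periodic window inside a closed vessel, and
#' a uniform density offset is held by the vessel's hydrostatic pressure,
#' not free to accelerate the window's fluid along the periodic axes.
#' Only deviations from the mean drive flow.
#'
#' @param fields a [field_set()].
#' @param metabolites named list of [metabolite_spec()].
#' @param env a [sim_environment()].
#' @param t simulated time, s.
#' @param subtract_mean remove the domain-mean buoyancy mode (default).
#' @return list of three cell-centered arrays `ax`, `ay`, `az` (m/s^2).
#' @export
boussinesq_buoyancy <- function(fields, metabolites, env, t = 0,
                                subtract_mean = TRUE) {
  gv <- gravity_body(env, t) + centrifugal_accel(env)
  B <- 0
  for (nm in names(metabolites)) {
    ms <- metabolites[[nm]]
    if (ms$beta != 0) B <- B + ms$beta * (fields$conc[[nm]] - ms$S_ref)
  }
  if (is.numeric(B) && length(B) == 1L) B <- array(B, dim = fields$grid$n)
  if (subtract_mean) B <- B - mean(B)
  list(ax = gv[1] * B, ay = gv[2] * B, az = gv[3] * B)
}

## spread a cell-centered array to x-faces (periodic), y-faces (wall-aware),
## z-faces (periodic)
.to_xface <- function(a) (a + .shiftp(a, 1L, -1L)) / 2
.to_zface <- function(a) (a + .shiftp(a, 3L, -1L)) / 2
.to_yface <- function(a) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2] + 1L, d[3]))
  out[, 2:d[2], ] <- (a[, 1:(d[2] - 1L), , drop = FALSE] +
                        a[, 2:d[2], , drop = FALSE]) / 2
  out[, d[2] + 1L, ] <- a[, d[2], ]       # one-sided at the outlet face
  out                                      # wall face (j = 1) stays 0
}

## first-order upwind advection term  (vel . grad) phi  for a face field
## phi, using advecting velocity components co-located with phi by simple
## averaging.  y derivatives use one-sided differences at the walls.
.upwind_advect <- function(phi, ax_vel, ay_vel, az_vel, h) {
  dgrad <- function(a, axis, hh, periodic) {
    if (periodic) {
      bwd <- (a - .shiftp(a, axis, -1L)) / hh
      fwd <- (.shiftp(a, axis, 1L) - a) / hh
    } else {
      d <- dim(a); n <- d[axis]
      idm <- c(1, pmax(seq_len(n) - 1L, 1L))[-1]
      idp <- c(pmin(seq_len(n) + 1L, n), n)[-(n + 1)]
      slice <- function(i) switch(axis, a[i, , , drop = FALSE],
                                  a[, i, , drop = FALSE],
                                  a[, , i, drop = FALSE])
      bwd <- (a - slice(idm)) / hh
      fwd <- (slice(idp) - a) / hh
    }
    list(bwd = bwd, fwd = fwd)
  }
  gx <- dgrad(phi, 1L, h[1], TRUE)
  gy <- dgrad(phi, 2L, h[2], FALSE)
  gz <- dgrad(phi, 3L, h[3], TRUE)
  up <- function(vel, g) {
    pos <- vel > 0
    vel * (g$bwd * pos + g$fwd * !pos)
  }
  up(ax_vel, gx) + up(ay_vel, gy) + up(az_vel, gz)
}

#' Advance the flow one time step
#'
#' One projection step: explicit upwind advection and frame/buoyancy
#' forcing, backward-Euler implicit viscosity, then an exact pressure
#' projection to a discretely divergence-free field.  The uniform
#' centrifugal body force is included and absorbed by the modified pressure;
#' the Coriolis acceleration acts on the local fluid velocity.  Advective
#' CFL is checked, not assumed.
#'
#' @param flow a [flow_state()].
#' @param fields a [field_set()] (metabolite concentrations for buoyancy).
#' @param env a [sim_environment()].
#' @param dt time step, s.
#' @param metabolites named list of [metabolite_spec()].
#' @param t simulated time at the start of the step, s.
#' @param div_tol maximum tolerated post-projection divergence, 1/s.
#' @param f_ext optional prescribed uniform body acceleration, length-3
#'   (m/s^2); used e.g. for forced-flow verification cases.
#' @return updated flow state (with `div_residual` diagnostic).
#' @export
step_fluid <- function(flow, fields, env, dt, metabolites, t = 0,
                       div_tol = 1e-8, f_ext = NULL) {
  grid <- fields$grid
  h <- grid$parcel_m
  n <- grid$n
  buo <- boussinesq_buoyancy(fields, metabolites, env, t)
  acc0 <- centrifugal_accel(env)
  if (!is.null(f_ext)) acc0 <- acc0 + f_ext
  fmax <- max(abs(buo$ax), abs(buo$ay), abs(buo$az)) + max(abs(acc0))
  umax <- max(abs(flow$u), abs(flow$v), abs(flow$w))
  if (umax == 0 && fmax == 0) {
    flow$div_residual <- 0
    attr(flow, "umax") <- 0
    return(flow)   # exactly quiescent: nothing can set the fluid in motion
  }
  cfl <- umax * dt / min(h)
  if (cfl > 1) {
    stop(sprintf("step_fluid: advective CFL %.3g > 1 (dt too large)", cfl))
  }
  uc <- flow_center_velocity(flow)
  ny <- n[2]
  ## --- explicit advection + forcing ---------------------------------
  ## cell-centered forcing: buoyancy + uniform centrifugal + Coriolis
  fx <- buo$ax + acc0[1] + 2 * env$omega * uc$v
  fy <- buo$ay + acc0[2] - 2 * env$omega * uc$u
  fz <- buo$az + acc0[3]
  if (cfl > 1e-6) {
    ## momentum advection matters only when the advective CFL is resolvable;
    ## at the creeping-flow Reynolds numbers of these scenarios (Re ~ 1e-6)
    ## the term is below round-off influence and is skipped
    adv_u <- .upwind_advect(flow$u, flow$u, .to_xface(uc$v), .to_xface(uc$w), h)
    adv_w <- .upwind_advect(flow$w, .to_zface(uc$u), .to_zface(uc$v), flow$w, h)
    adv_v <- .upwind_advect(flow$v, .to_yface(uc$u), flow$v, .to_yface(uc$w), h)
  } else {
    adv_u <- 0; adv_w <- 0; adv_v <- 0
  }
  us <- flow$u + dt * (-adv_u + .to_xface(fx))
  ws <- flow$w + dt * (-adv_w + .to_zface(fz))
  vs <- flow$v + dt * (-adv_v + .to_yface(fy))
  vs[, 1, ] <- 0                      # no-slip outer wall
  ## --- implicit viscosity --------------------------------------------
  cv <- env$nu * dt
  us <- .helmholtz_solve(us, cv, grid, "wall", "neumann")
  ws <- .helmholtz_solve(ws, cv, grid, "wall", "neumann")
  vi <- .helmholtz_solve(vs[, 2:ny, , drop = FALSE], cv, grid,
                         "dirichlet0", "neumann")
  vs[, 2:ny, ] <- vi
  vs[, ny + 1L, ] <- vs[, ny, ]       # zero-gradient outlet estimate
  ## --- projection -----------------------------------------------------
  tmp <- flow
  tmp$u <- us; tmp$v <- vs; tmp$w <- ws
  div <- flow_divergence(tmp, grid)
  phi <- .poisson_solve(div / dt, grid)
  us <- us - dt * (phi - .shiftp(phi, 1L, -1L)) / h[1]
  ws <- ws - dt * (phi - .shiftp(phi, 3L, -1L)) / h[3]
  gy <- array(0, dim(vs))
  gy[, 2:ny, ] <- (phi[, 2:ny, , drop = FALSE] -
                     phi[, 1:(ny - 1L), , drop = FALSE]) / h[2]
  gy[, ny + 1L, ] <- (-2 * phi[, ny, , drop = FALSE]) / h[2]  # p = 0 at face
  vs <- vs - dt * gy
  vs[, 1, ] <- 0
  flow$u <- us; flow$v <- vs; flow$w <- ws
  flow$p <- phi   # modified pressure (per unit density) up to the BC gauge
  attr(flow, "umax") <- max(abs(us), abs(vs), abs(ws))
  flow$div_residual <- max(abs(flow_divergence(flow, grid)))
  if (flow$div_residual > div_tol) {
    stop(sprintf("step_fluid: post-projection divergence %.3g exceeds %.3g",
                 flow$div_residual, div_tol))
  }
  flow
}
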