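test_that("Stokes drag has the creeping-flow magnitude and direction", {
  v <- matrix(c(1e-6, 0, 0), 1)
  u <- matrix(0, 1, 3)
  expect_equal(stokes_drag_force(1e-6, 1e-3, u, u), matrix(0, 1, 3))
  F <- stokes_drag_force(1e-6, 1e-3, v, u)
  expect_equal(sqrt(sum(F^2)), 6 * pi * 1e-6 * 1e-3 * 1e-6, tolerance = 1e-12)
  expect_lt(F[1], 0)  # opposes relative motion
  F2 <- stokes_drag_force(2e-6, 1e-3, v, u)
  expect_equal(F2, 2 * F)
  expect_error(stokes_drag_force(0, 1e-3, v, u), "radius")
})

test_that("body-frame acceleration decomposes per term and sums exactly", {
  grid <- default_grid()
  params <- default_species()
  cells <- make_cells(matrix(c(150, 50, 150), 1), "ECOLI", params)
  u0 <- matrix(0, 1, 3)

  ## neutral buoyancy at rest: everything vanishes
  env_nb <- sim_environment("RWV", rho_s = 1000)
  a <- body_frame_acceleration(cells, env_nb, u0)
  expect_equal(max(abs(a$a_total)), 0)

  ## centrifugal magnitude at 10 RPM, 1 cm arm, specific-gravity 1/11
  env <- sim_environment("RWV")
  a <- body_frame_acceleration(cells, env, u0)
  expect_equal(sqrt(sum(a$a_centrifugal^2)), 9.969e-4, tolerance = 1e-3)
  ## it points radially outward (toward the outer wall at y = 0)
  expect_lt(a$a_centrifugal[2], 0)

  ## Coriolis of x-motion is -2 omega v along y (hand cross-product)
  cells$vx <- 1e-6
  a <- body_frame_acceleration(cells, env, u0)
  expect_equal(a$a_coriolis[1, ], c(0, -2 * env$omega * 1e-6, 0))

  ## decomposition sums to the total at machine precision
  expect_equal(a$a_total,
               a$a_centrifugal + a$a_coriolis + a$a_gravity + a$a_drag)

  ## limits: omega -> 0 kills centrifugal and Coriolis
  env0 <- sim_environment("ONE_G")
  a0 <- body_frame_acceleration(cells, env0, u0)
  expect_equal(max(abs(a0$a_centrifugal)), 0)
  expect_equal(max(abs(a0$a_coriolis)), 0)
  ## matched velocities kill drag
  cells$vx <- 0
  a1 <- body_frame_acceleration(cells, env0, u0)
  expect_equal(max(abs(a1$a_drag)), 0)
  expect_error(body_frame_acceleration(transform(cells, r_um = 0), env0, u0),
               "radius")
})

test_that("quasi-steady velocity solves the force balance with Coriolis", {
  set.seed(7)
  env <- sim_environment("RWV")
  for (i in 1:20) {
    r_m <- um_to_m(runif(1, 0.2, 2))
    u_f <- matrix(rnorm(3, sd = 1e-6), 1)
    a_ext <- matrix(rnorm(3, sd = 1e-3), 1)
    v <- terminal_velocity(env, u_f, a_ext, r_m)
    ## independent oracle: dense 3x3 solve of (c I + 2 Omega x) v = c u + a
    cdr <- 4.5 * (env$rho_f / env$rho_s) * env$nu / r_m^2
    W <- matrix(c(0, -2 * env$omega, 0,
                  2 * env$omega, 0, 0,
                  0, 0, 0), 3, 3)   # rows: 2 omega x v with omega || z
    A <- diag(cdr, 3) + t(W)
    v_ref <- solve(A, as.numeric(cdr * u_f + a_ext))
    expect_equal(as.numeric(v), v_ref, tolerance = 1e-10)
    ## residual of the full acceleration balance is zero
    cells <- make_cells(matrix(c(150, 50, 150), 1), "ECOLI")
    cells$r_um <- m_to_um(r_m)
    cells$vx <- v[1]; cells$vy <- v[2]; cells$vz <- v[3]
    aB <- cdr * (u_f - v) + a_ext +
      c(2 * env$omega * v[2], -2 * env$omega * v[1], 0)
    expect_lt(max(abs(aB)) / max(abs(a_ext)), 1e-10)
  }
})

test_that("settling speed matches the Stokes terminal-velocity closed form", {
  env <- sim_environment("ONE_G", rho_f = 1000, rho_s = 1100)
  grid <- default_grid()
  fields <- make_fields(grid)
  cells <- make_cells(matrix(c(150, 50, 150), 1), "ECOLI")
  out <- integrate_cells(cells, fields, env, dt = 1, t = 0)
  v_ref <- (2 / 9) * 100 * 9.81 * um_to_m(0.470077)^2 / 1e-3
  expect_equal(abs(out$vy), v_ref, tolerance = 0.01)
  expect_lt(out$vy, 0)   # settles toward the floor
})

test_that("microgravity quiescent fluid leaves every placement fixed", {
  env <- sim_environment("MICROGRAVITY")
  fields <- make_fields()
  set.seed(3)
  pos <- cbind(runif(20, 0, 300), runif(20, 1, 99), runif(20, 0, 300))
  cells <- make_cells(pos)
  out <- cells
  for (i in 1:5) out <- integrate_cells(out, fields, env, dt = 10, t = i)
  expect_equal(cbind(out$x, out$y, out$z), pos, tolerance = 1e-14)
})

test_that("neutrally buoyant cells advect exactly with the fluid in the RWV", {
  env <- sim_environment("RWV", rho_s = 1000)
  fields <- make_fields()
  fields$flow$u[] <- 2e-6
  attr(fields$flow, "umax") <- 2e-6
  cells <- make_cells(matrix(c(150, 50, 150), 1), "ECOLI")
  out <- integrate_cells(cells, fields, env, dt = 1)
  expect_equal(out$vx, 2e-6, tolerance = 1e-6 * 2e-6)
  ## a residual Coriolis drift of order 2 omega u / c_drag remains
  expect_lt(abs(out$vy), 1e-12)
})

test_that("periodic wrapping preserves the cell count and the domain bounds", {
  env <- sim_environment("ONE_G")
  grid <- default_grid()
  fields <- make_fields(grid)
  set.seed(11)
  pos <- cbind(runif(50, 0, 300), runif(50, 0.5, 99.5), runif(50, 0, 300))
  cells <- make_cells(pos)
  out <- integrate_cells(cells, fields, env, dt = 3600)  # one hour: hits wall
  expect_identical(nrow(out), 50L)
  expect_true(all(out$x >= 0 & out$x < 300))
  expect_true(all(out$z >= 0 & out$z < 300))
  expect_true(all(out$y >= out$r_um - 1e-12 & out$y <= 100 - out$r_um + 1e-12))
  expect_gt(attr(out, "wall_events"), 0)  # clamps counted, never lost
  expect_true(all(out$vy[out$y <= out$r_um + 1e-9] == 0))
})

test_that("rigid-colony mode gives all members one shared velocity", {
  env <- sim_environment("ONE_G")
  fields <- make_fields()
  set.seed(5)
  pos <- cbind(runif(10, 140, 160), runif(10, 40, 60), runif(10, 140, 160))
  cells <- make_cells(pos)
  out <- integrate_cells(cells, fields, env, dt = 1, mode = "RIGID_COLONY")
  expect_equal(length(unique(out$vy)), 1L)
  ## identical cells: the shared velocity equals the individual one
  ind <- integrate_cells(cells, fields, env, dt = 1, mode = "INDIVIDUAL")
  expect_equal(out$vy[1], ind$vy[1], tolerance = 1e-12)
})

test_that("static (wall-attached) mode does not move cells", {
  env <- sim_environment("ONE_G")
  fields <- make_fields()
  cells <- make_cells(matrix(c(150, 5, 150), 1), "ECOLI")
  out <- integrate_cells(cells, fields, env, dt = 100, mode = "STATIC")
  expect_equal(out$y, cells$y)
  expect_identical(out$vy, 0)
})
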