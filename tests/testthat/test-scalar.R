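test_that("void fraction counts occupied parcel volume and floors safely", {
  grid <- default_grid()
  params <- default_species()
  expect_equal(compute_void_fraction(make_cells(matrix(numeric(0), 0, 3)),
                                     grid, params),
               array(1, grid$n))
  ## one half-cubic-micron cell in a 500 um^3 parcel
  p <- species_params("ECOLI", mu_max = 1.82e-5, V_cell = 0.5,
                      limiting_substrate = "methionine", product = "acetate",
                      yield_product = 1.86)
  cells <- new_cells("ECOLI", matrix(c(150, 50, 150), 1), list(ECOLI = p))
  eps <- compute_void_fraction(cells, grid, list(ECOLI = p))
  idx <- parcel_index(matrix(c(150, 50, 150), 1), grid)
  expect_equal(eps[idx], 1 - 0.5 / 500)

  ## ~430 default cells fill a parcel to the random-packing fraction
  ## (parcel (31, 3, 31): x, z in [150, 155), y in [40, 60))
  set.seed(8)
  pos <- cbind(runif(430, 150.1, 154.9), runif(430, 40.1, 59.9),
               runif(430, 150.1, 154.9))
  cells430 <- make_cells(pos, rep("ECOLI", 430))
  eps430 <- compute_void_fraction(cells430, grid, params)
  expect_equal(eps430[idx], 1 - 430 * 0.436 / 500, tolerance = 1e-12)
  expect_equal(1 - 430 * 0.436 / 500, 0.625, tolerance = 1e-3)

  ## overcrowding warns and floors
  pos2 <- matrix(rep(c(150, 50, 150), each = 1500), 1500, 3)
  cells2 <- make_cells(pos2, rep("ECOLI", 1500))
  expect_warning(eps2 <- compute_void_fraction(cells2, grid, params),
                 "overcrowded")
  expect_gte(min(eps2), 0.4)
})

test_that("uniform fields are fixed points of transport", {
  grid <- default_grid()
  S <- array(2.5e-4, grid$n)
  out <- step_scalar(S, NULL, 5e-10, 0.1, grid)
  attr(out, "outflow_ce") <- NULL
  expect_equal(out, S)
})

test_that("point release matches the reflected/wrapped heat kernel", {
  grid <- default_grid()
  D <- 5e-10
  S <- array(0, grid$n)
  S[31, 3, 31] <- 1      # release at a parcel center
  m0 <- 1 * grid$V_parcel_um3
  dt <- 0.05
  tend <- 10
  for (i in seq_len(tend / dt)) S <- step_scalar(S, NULL, D, dt, grid)
  ## oracle: free-space Gaussian, periodically wrapped in x/z and reflected
  ## at the y walls (method of images), evaluated at parcel centers
  D_um <- D * 1e12
  s2 <- 2 * D_um * tend
  g1 <- function(d, L, images = 3) {
    out <- 0
    for (k in -images:images) out <- out + exp(-(d + k * L)^2 / (2 * s2))
    out / sqrt(2 * pi * s2)
  }
  grefl <- function(d_direct, y, y0, L, images = 3) {
    out <- 0
    for (k in -images:images) {
      out <- out + exp(-(y - y0 + 2 * k * L)^2 / (2 * s2)) +
        exp(-(y + y0 + 2 * k * L)^2 / (2 * s2))
    }
    out / sqrt(2 * pi * s2)
  }
  cx <- (seq_len(60) - 0.5) * 5; cy <- (seq_len(5) - 0.5) * 20
  x0 <- 30.5 * 5; y0 <- 2.5 * 20
  gx <- g1(cx - x0, 300)
  gy <- grefl(NULL, cy, y0, 100)
  gz <- g1(cx - x0, 300)
  ref <- m0 * outer(outer(gx, gy), gz)
  dim(ref) <- grid$n
  expect_lt(sqrt(sum((S - ref)^2) / sum(ref^2)), 0.02)
})

test_that("diffusion conserves mass, stays nonnegative, contracts in Linf", {
  grid <- default_grid()
  set.seed(31)
  S <- array(runif(prod(grid$n)), grid$n)
  tot0 <- sum(S)
  hi0 <- max(S); lo0 <- min(S)
  for (i in 1:50) S <- step_scalar(S, NULL, 1e-9, 0.1, grid)
  expect_equal(sum(S), tot0, tolerance = 1e-12)
  expect_gte(min(S), 0)
  expect_lte(max(S), hi0 + 1e-12)
  expect_gte(min(S), lo0 - 1e-12)
})

test_that("steady diffusive flux between pinned parcels doubles with D", {
  grid <- default_grid()
  flux_at <- function(D) {
    S <- array(0, grid$n)
    hi <- c(28, 3, 30); lo <- c(34, 3, 30)   # close pair: fast relaxation
    for (i in 1:600) {                # converge the pinned steady profile
      S[hi[1], hi[2], hi[3]] <- 1
      S[lo[1], lo[2], lo[3]] <- 0
      S <- step_scalar(S, NULL, D, 0.5, grid)
    }
    ## diffusive efflux from the pinned source through its six faces
    S[hi[1], hi[2], hi[3]] <- 1
    S[lo[1], lo[2], lo[3]] <- 0
    D_um <- D * 1e12
    h <- grid$parcel_um
    nb <- function(di, dj, dk, hh) {
      (1 - S[hi[1] + di, hi[2] + dj, hi[3] + dk]) / hh^2
    }
    D_um * (nb(1, 0, 0, h[1]) + nb(-1, 0, 0, h[1]) +
              nb(0, 1, 0, h[2]) + nb(0, -1, 0, h[2]) +
              nb(0, 0, 1, h[3]) + nb(0, 0, -1, h[3]))
  }
  f1 <- flux_at(5e-10)
  f2 <- flux_at(1e-9)
  expect_gte(f2 / f1, 1.8)
})

test_that("advection uses conservative upwind fluxes", {
  grid <- default_grid()
  fl <- flow_state(grid)
  fl$u[] <- 5e-6                      # uniform x-wind, periodic
  attr(fl, "umax") <- 5e-6
  set.seed(4)
  S <- array(0, grid$n)
  S[20:25, , 20:25] <- 1e-3
  tot0 <- sum(S)
  for (i in 1:40) S <- step_scalar(S, fl, 1e-12, 0.1, grid)
  expect_equal(sum(S), tot0, tolerance = 1e-12)   # periodic: no loss
  expect_gte(min(S), 0)
})

test_that("film exchange relaxes pools exponentially and conserves mass", {
  grid <- default_grid()
  env <- sim_environment("MICROGRAVITY")
  params <- default_species()
  ## tiny diffusivity makes the film slow enough to observe the transient
  mets <- default_metabolites(1e-16, beta = 0)
  fields <- field_set(grid, mets, init_conc = c(lactose = 1e-3))
  cells <- make_cells(matrix(c(150, 50, 150), 1), "ECOLI", params)
  cells$pool_pro <- 0.01
  tot0 <- 0.01 + sum(fields$conc$acetate) * 500

  dt <- 5
  ex <- exchange_with_cells(cells, fields, env, params, mets, dt,
                            pool = "product")
  ## independent oracle: hand-evaluated film law (quiescent sphere, Sh = 2
  ## at unit void fraction, two-compartment exact solution)
  r <- cells$r_um
  Sh <- 2
  h_um <- Sh * (1e-16 * 1e12) / (2 * r)       # um/s
  a <- 4 * pi * r^2 * h_um
  Vc <- 0.436; Vp <- 500
  kap <- a * (1 / Vc + 1 / Vp)
  Ceq <- 0.01 / (Vc + Vp)
  pool_ref <- Ceq * Vc + (0.01 - Ceq * Vc) * exp(-kap * dt)
  expect_equal(ex$cells$pool_pro, pool_ref, tolerance = 1e-9)
  expect_lt(ex$cells$pool_pro, 0.01)          # monotone release
  tot1 <- ex$cells$pool_pro + sum(ex$fields$conc$acetate) * 500
  expect_equal(tot1, tot0, tolerance = 1e-12)

  ## equilibrium: no exchange
  cells_eq <- ex$cells
  cells_eq$pool_pro <- 0.436 * ex$fields$conc$acetate[31, 3, 31]
  fields_eq <- ex$fields
  ex2 <- exchange_with_cells(cells_eq, fields_eq, env, params, mets, dt,
                             pool = "product")
  expect_equal(ex2$cells$pool_pro, cells_eq$pool_pro, tolerance = 1e-6)
})

test_that("film uptake rate has the A_C h_S magnitude", {
  ## r = 0.47 um: A_C = 4 pi r^2 = 2.776 um^2 = 2.776e-12 m^2, and with
  ## h_S = 1.06e-3 m/s a unit concentration difference drives
  ## A_C h_S dS ~ 2.94e-15 (volume flux in m^3/s before normalization)
  A_C <- 4 * pi * um_to_m(0.47)^2
  expect_equal(A_C, 2.776e-12, tolerance = 1e-3)
  expect_equal(A_C * 1.06e-3 * 1, 2.94e-15, tolerance = 1e-2)
})
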