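test_that("Sherwood correlation hits its closed-form anchor points", {
  expect_equal(sherwood(1, 0, 2000), 2)       # quiescent isolated sphere
  expect_equal(sherwood(0.9, 0, 2000), 2.05)  # 7 - 9 + 4.05
  ## at Re = 0 the result is Sc-independent
  expect_equal(sherwood(0.8, 0, 10), sherwood(0.8, 0, 1e5))
  expect_warning(out <- sherwood(1, 150, 100), "clamped")
  expect_equal(out, sherwood(1, 100, 100))
  expect_error(sherwood(0, 1, 100), "eps")
  expect_error(sherwood(1, -1, 100), "Re_P")
})

test_that("pipeline h_S equals the hand-evaluated correlation on random draws", {
  set.seed(12)
  n <- 100
  eps <- runif(n, 0.5, 1)
  Re <- 10^runif(n, -9, 1.9)
  Sc <- 10^runif(n, 2, 4.5)
  D <- 1e-6 / Sc                       # so Sc = nu/D with nu = 1e-6
  r <- um_to_m(runif(n, 0.2, 1.5))
  h <- mass_transfer_coefficient(sherwood(eps, Re, Sc), D, r)
  h_ref <- sherwood_by_hand(eps, Re, Sc) * D / (2 * r)
  expect_equal(h, h_ref, tolerance = 1e-12)
})

test_that("the quiescent transfer coefficient matches the printed value", {
  ## Sh = 2, D = 5e-10 m^2/s, r = 0.47 um -> 1.06e-3 m/s
  h <- mass_transfer_coefficient(2, 5e-10, um_to_m(0.47))
  expect_equal(h, 1.06e-3, tolerance = 5e-3)
  expect_equal(mass_transfer_coefficient(4, 5e-10, um_to_m(0.47)), 2 * h)
})

test_that("half-saturation constant is inversely proportional to h_S", {
  sp <- default_species()$ECOLI
  K1 <- monod_Ks(1.06e-3, sp)
  K2 <- monod_Ks(2.12e-3, sp)
  expect_equal(K2, K1 / 2, tolerance = 1e-12)
  expect_gt(K1, 0)
  ## the microgravity-to-RWV coefficient change cuts K_S by ~9%
  K_rwv <- monod_Ks(1.17e-3, sp)
  expect_equal(100 * (1 - K_rwv / K1), 9.4, tolerance = 0.01)
  expect_error(monod_Ks(0, sp), "h_S")
})

test_that("growth follows Monod in the transmembrane difference", {
  mu_max <- 1.82e-5
  K <- 1.2e-8
  expect_equal(growth_rate(K, 0, mu_max, K), mu_max / 2)
  expect_equal(growth_rate(3 * K, 0, mu_max, K), 0.75 * mu_max)
  expect_equal(growth_rate(1e6 * K, 0, mu_max, K), mu_max, tolerance = 1e-5)
  ## reversed gradient clamps to zero: anabolic growth only
  expect_identical(growth_rate(1e-9, 2e-9, mu_max, K), 0)
  ## monotone nondecreasing, bounded by mu_max
  dS <- sort(10^runif(50, -12, -6))
  mu <- growth_rate(dS, 0, mu_max, K)
  expect_true(all(diff(mu) >= 0))
  expect_true(all(mu >= 0 & mu <= mu_max))
})

test_that("zero-order conversion respects pools, yields, and co-substrate", {
  params <- default_species()
  cells <- make_cells(rbind(c(10, 50, 10), c(20, 50, 20)),
                      c("ECOLI", "SENTERICA"), params)
  ## empty pools: nothing happens
  out <- convert_substrate(cells, params, dt = 100)
  expect_equal(out$pool_pro, c(0, 0))

  ## S. enterica: 1 cell equivalent acetate -> Y_MA methionine
  cells$pool_sub <- 1
  dt_big <- 2 / params$SENTERICA$k_convert
  out <- convert_substrate(cells, params, dt = dt_big)
  i_s <- which(cells$species == "SENTERICA")
  expect_equal(out$pool_pro[i_s], params$SENTERICA$yield_product * 1)
  expect_equal(out$pool_sub[i_s], 0)

  ## E. coli with methionine but no lactose: no conversion
  cells2 <- cells
  out2 <- convert_substrate(cells2, params, dt = dt_big,
                            lactose_available = c(0, Inf))
  i_e <- which(cells$species == "ECOLI")
  expect_equal(out2$pool_pro[i_e], 0)
  expect_equal(out2$pool_sub[i_e], 1)

  ## with lactose, E. coli yields Y_AM acetate per methionine
  out3 <- convert_substrate(cells2, params, dt = dt_big)
  expect_equal(out3$pool_pro[i_e], params$ECOLI$yield_product * 1)
})

test_that("mass update is exponential, matching Euler to first order", {
  expect_identical(update_mass(1, 0, 100), 1)
  ## mu_max for E. coli over five minutes
  expect_equal(update_mass(1, 1.82e-5, 300), exp(5.46e-3))
  expect_equal(update_mass(1, 1.82e-5, 300), 1.00547, tolerance = 1e-5)
  mu <- 1e-6; dt <- 10   # mu dt = 1e-5
  expect_equal(update_mass(2, mu, dt), 2 * (1 + mu * dt), tolerance = 1e-9)
  expect_error(update_mass(1, -1e-6, 1), "mu")
})

test_that("cell kinetics solve the film balance per regime", {
  grid <- default_grid()
  env <- sim_environment("MICROGRAVITY")
  params <- default_species()
  mets <- default_metabolites("intermediate")
  fields <- field_set(grid, mets)
  cells <- make_cells(matrix(c(150, 50, 150), 1), "SENTERICA", params)

  ## abundant substrate: demand-limited, dS = k m / (A_C h_S) and the
  ## conversion runs at k m
  fields$conc$acetate[] <- 1e-6
  kin <- cell_kinetics(cells, fields, env, params, mets)
  a <- 4 * pi * cells$r_um^2 * m_to_um(kin$h_sub)
  expect_false(kin$supply_limited)
  expect_equal(kin$conv_rate, params$SENTERICA$k_convert * 1)
  expect_equal(kin$dS, kin$conv_rate / a, tolerance = 1e-12)
  expect_equal(kin$mu,
               growth_rate(kin$dS, 0, params$SENTERICA$mu_max, kin$K_S))

  ## the demand-limited growth ceiling is mu_max * Y_XS/(1 + Y_XS):
  ## dS/K_S = m Y_XS identically (geometry cancels h_S)
  expect_equal(kin$dS / kin$K_S, params$SENTERICA$Y_XS, tolerance = 1e-9)

  ## scarce substrate: supply-limited at A_C h_S S_f
  fields$conc$acetate[] <- 1e-12
  kin2 <- cell_kinetics(cells, fields, env, params, mets)
  expect_true(kin2$supply_limited)
  expect_equal(kin2$conv_rate, a * 1e-12, tolerance = 1e-9)
  expect_equal(kin2$dS, 1e-12)
})

test_that("sedimentation raises the transfer coefficient as in the RWV", {
  grid <- default_grid()
  params <- default_species()
  mets <- default_metabolites("intermediate")
  env <- sim_environment("RWV")
  fields <- field_set(grid, mets)
  cells <- make_cells(matrix(c(150, 50, 150), 1), "ECOLI", params)
  ## quasi-steady sedimentation under the rotating 1 g vector
  cells <- integrate_cells(cells, fields, env, dt = 0.1, t = 0)
  kin <- cell_kinetics(cells, fields, env, params, mets)
  v_sed <- (2 / 9) * 100 * 9.81 * um_to_m(cells$r_um)^2 / 1e-3
  Re_ref <- v_sed * 2 * um_to_m(cells$r_um) / 1e-6
  expect_equal(kin$Re_P, Re_ref, tolerance = 1e-2)
  ## hand-evaluated enhancement over the quiescent coefficient (eps = 1
  ## here: the void-fraction field was not populated for this single cell);
  ## the slip speed additionally carries a small Coriolis component
  h_ref <- sherwood_by_hand(1, Re_ref, 2000) * 5e-10 /
    (2 * um_to_m(cells$r_um))
  expect_equal(kin$h_sub, h_ref, tolerance = 1e-3)
  expect_gt(kin$h_sub, mass_transfer_coefficient(2, 5e-10,
                                                 um_to_m(cells$r_um)))
})
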