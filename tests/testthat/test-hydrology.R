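cfg0 <- sim_config()

test_that("infiltration matches hand calculation and saturates correctly", {
  ## bare soil: alpha*O*W0 = 0.1*20*0.15 = 0.3, equal to rainfall at the
  ## bare-soil equilibrium O for R0 = 0.3
  expect_equal(infiltration(20, 0, cfg0), 0.3)
  expect_equal(infiltration(0, 100, cfg0), 0)
  ## vegetated limit -> alpha*O
  expect_equal(infiltration(20, 1e12, cfg0), cfg0$alpha * 20,
               tolerance = 1e-6)
  ## monotone increasing in biomass
  fl <- infiltration(20, seq(0, 2000, by = 50), cfg0)
  expect_true(all(diff(fl) > 0))
  expect_true(all(fl >= cfg0$alpha * 20 * cfg0$W0 - 1e-12 &
                  fl <= cfg0$alpha * 20 + 1e-12))
})

test_that("the literal water-denominator infiltration variant is available", {
  cfgw <- sim_config(infiltration_denominator = "water")
  expect_error(infiltration(20, 0, cfgw), "soil water")
  ## denominator W + k2 instead of P + k2
  expect_equal(infiltration(20, 16, cfgw, W = 3),
               0.1 * 20 * (1 + 5 * 0.15) / (3 + 5))
})

test_that("uptake is Michaelis-Menten in W and linear in biomass density", {
  ## W = k1 halves g_max; 160 g on a 16 m2 parcel = 10 g/m2
  expect_equal(uptake_field(3, 160, cfg0), 0.05 * 0.5 * 10)
  expect_equal(uptake_field(3, 0, cfg0), 0)
  expect_equal(uptake_field(0, 500, cfg0), 0)
  ## saturation limit g_max * P
  expect_equal(uptake_field(1e9, 160, cfg0), 0.05 * 10, tolerance = 1e-6)
})

test_that("laplacian reproduces the 5-point stencil with both boundaries", {
  expect_equal(laplacian(matrix(c(0, 1, 0), 1, 3), dx = 1),
               matrix(c(1, -2, 1), 1, 3))
  expect_equal(laplacian(matrix(5, 7, 4), dx = 2), matrix(0, 7, 4))
  ## zero-flux conserves the discrete total
  set.seed(1)
  f <- matrix(runif(48), 6, 8)
  expect_equal(sum(laplacian(f, dx = 4)), 0, tolerance = 1e-12)
  ## periodic wraps: a single spike spreads to wrapped neighbors
  g <- matrix(0, 3, 3); g[1, 1] <- 1
  lp <- laplacian(g, dx = 1, boundary = "periodic")
  expect_equal(lp[1, 1], -4)
  expect_equal(lp[3, 1], 1)  # wrapped x neighbor
  expect_equal(lp[1, 3], 1)  # wrapped y neighbor
  expect_equal(sum(lp), 0, tolerance = 1e-12)
  expect_error(laplacian(1:5, dx = 1), "matrix")
})

test_that("bare-soil equilibrium is a fixed point of the water integrator", {
  cfg <- sim_config(rain = rainfall_regime("constant", R0 = 0.3),
                    nx = 6, ny = 6)
  g0 <- bare_soil_grid(cfg)
  g <- g0
  Bsum <- matrix(0, 6, 6)
  for (i in 1:200) g <- water_step(g, Bsum, cfg, dt = 1)
  expect_lt(max(abs(g$O - g0$O)) / max(g0$O), 1e-6)
  expect_lt(max(abs(g$W - g0$W)) / max(g0$W), 1e-6)
})

test_that("without rain, plants and diffusion, soil water decays exponentially", {
  cfg <- sim_config(rain = rainfall_regime("constant", R0 = 0),
                    D_O = 0, D_W = 0, nx = 3, ny = 3)
  g <- new_soil_grid <- structure(
    list(O = matrix(0, 3, 3), W = matrix(8, 3, 3), dx = 4),
    class = "soil_grid")
  t_total <- 10
  for (i in seq_len(t_total)) g <- water_step(g, matrix(0, 3, 3), cfg, dt = 1)
  expect_equal(g$W[2, 2], 8 * exp(-cfg$r_w * t_total), tolerance = 1e-8)
  expect_true(all(g$O == 0))
})

test_that("RK4 water integration agrees with a fine explicit-Euler oracle", {
  cfg <- sim_config(rain = rainfall_regime("constant", R0 = 1.0),
                    nx = 5, ny = 5, dt_int = 0.02)
  set.seed(8)
  O <- matrix(runif(25, 30, 80), 5, 5)
  W <- matrix(runif(25, 2, 12), 5, 5)
  Bsum <- matrix(0, 5, 5); Bsum[c(7, 13, 19)] <- c(200, 450, 90)
  g <- structure(list(O = O, W = W, dx = 4), class = "soil_grid")
  for (i in 1:5) g <- water_step(g, Bsum, cfg, dt = 1)
  ref <- oracle_water_euler(O, W, Bsum, oracle_params(cfg), R = 1.0,
                            t_total = 5, h = 0.0002)
  expect_lt(max(abs(g$O - ref$O)) / max(ref$O), 1e-3)
  expect_lt(max(abs(g$W - ref$W)) / max(ref$W), 1e-3)
})

test_that("halving the integration step leaves the solution unchanged", {
  set.seed(12)
  O <- matrix(runif(25, 30, 80), 5, 5)
  W <- matrix(runif(25, 2, 12), 5, 5)
  Bsum <- matrix(rexp(25, 1 / 100), 5, 5)
  run_with <- function(h) {
    cfg <- sim_config(rain = rainfall_regime("constant", R0 = 1.0),
                      nx = 5, ny = 5, dt_int = h)
    g <- structure(list(O = O, W = W, dx = 4), class = "soil_grid")
    for (i in 1:10) g <- water_step(g, Bsum, cfg, dt = 1)
    g
  }
  g1 <- run_with(0.02)
  g2 <- run_with(0.01)
  expect_lt(max(abs(g1$O - g2$O)) / max(g2$O), 1e-4)
  expect_lt(max(abs(g1$W - g2$W)) / max(g2$W), 1e-4)
})

test_that("water budget closes under zero-flux boundaries", {
  ## d/dt (sum O + sum W) must equal sum(R - r_w W - uptake): diffusion
  ## moves water around but cannot create or destroy it.
  cfg <- sim_config(rain = rainfall_regime("constant", R0 = 1.0),
                    nx = 8, ny = 8, dt_int = 0.01)
  set.seed(3)
  O <- matrix(runif(64, 30, 70), 8, 8)
  W <- matrix(runif(64, 3, 10), 8, 8)
  Bsum <- matrix(rexp(64, 1 / 80), 8, 8)
  g0 <- structure(list(O = O, W = W, dx = 4), class = "soil_grid")
  h <- 0.01
  g1 <- water_step(g0, Bsum, cfg, dt = h)
  lhs <- (sum(g1$O) + sum(g1$W) - sum(g0$O) - sum(g0$W)) / h
  mid <- list(O = (g0$O + g1$O) / 2, W = (g0$W + g1$W) / 2)
  rhs <- sum(1.0 - cfg$r_w * mid$W - uptake_field(mid$W, Bsum, cfg))
  expect_equal(lhs, rhs, tolerance = 1e-5)
})
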