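cfg0 <- sim_config()

test_that("growth rate matches hand evaluations of the biomass equation", {
  expect_equal(growth_rate(0, 5, cfg0), 0)
  ## no water: pure turnover -B*d
  expect_equal(growth_rate(10, 0, cfg0), -3)
  ## B = 1 g at W = k1 = 3: 1*10*0.05*(1 - 1/800)*0.5 - 0.3
  expect_equal(growth_rate(1, 3, cfg0), -0.0503125)
  ## water saturation: at W >> k1 and small B, rate -> b*g_max - d = 0.2
  expect_equal(growth_rate(1, 1e9, cfg0), 1 * (10 * 0.05 * (1 - 1 / 800) - 0.3),
               tolerance = 1e-6)
})

test_that("growth rate is non-decreasing in local soil water", {
  for (B in c(0.5, 1, 50, 400)) {
    r <- growth_rate(B, seq(0, 40, by = 0.5), cfg0)
    expect_true(all(diff(r) >= 0))
  }
})

test_that("biomass never exceeds the size cap and approaches its equilibrium", {
  ## with abundant water the equilibrium solves
  ## b*g_max*(1 - B/Kp)*W/(W+k1) = d; for W -> Inf: B* = Kp(1 - d/(b g_max))
  p <- oracle_params(cfg0)
  Bstar <- cfg0$Kp * (1 - cfg0$d / (cfg0$b * cfg0$g_max))
  expect_equal(Bstar, 320)
  B <- oracle_plant_euler(1, 1e9, p, t_total = 200, h = 0.01)
  expect_equal(B, Bstar, tolerance = 1e-3)
  expect_lt(B, cfg0$Kp)
  ## at the soil water the footnoted ~120 g "effective maximum" implies
  ## (W about 7.2), the equilibrium is indeed about 120 g
  W120 <- 7.2
  Bstar_w <- cfg0$Kp * (1 - cfg0$d * (W120 + cfg0$k1) /
                          (cfg0$b * cfg0$g_max * W120))
  expect_equal(Bstar_w, 120, tolerance = 0.01)
})

test_that("early growth without turnover is exponential at rate b*g_max", {
  cfg <- sim_config(d = 0)
  p <- oracle_params(cfg)
  p$d <- 0
  tt <- seq(0, 4, by = 1)
  B <- vapply(tt, function(t) oracle_plant_euler(0.01, 1e9, p, t, 0.001),
              numeric(1))
  fit <- stats::lm(log(B) ~ tt)
  expect_equal(unname(stats::coef(fit)[2]), cfg$b * cfg$g_max,
               tolerance = 0.02)
})

test_that("metabolism step agrees with a fine-step reference integration", {
  cfg <- sim_config(nx = 4, ny = 4, dt_int = 0.02)
  grid <- structure(list(O = matrix(40, 4, 4), W = matrix(6, 4, 4), dx = 4),
                    class = "soil_grid")
  pop <- new_population(id = 1L, x = 2, y = 2, age = 100, B = 2)
  for (i in seq_len(30 / cfg$dt_event))
    pop <- metabolism_step(pop, grid, cfg)
  ref <- oracle_plant_euler(2, 6, oracle_params(cfg), t_total = 30,
                            h = 0.0005)
  expect_lt(abs(pop$B - ref), 1e-4)
  expect_equal(pop$Bmax, pop$B)  # monotone growth here
  ## dt = 0 is the identity
  expect_equal(metabolism_step(pop, grid, cfg, dt = 0), pop)
})

test_that("per-plant demand is linear and sums to the parcel uptake", {
  expect_equal(plant_water_demand(5, 4, cfg0) + plant_water_demand(5, 4, cfg0),
               plant_water_demand(10, 4, cfg0))
  expect_equal(plant_water_demand(10, 0, cfg0), 0)
  B <- c(3, 40, 120, 0.7)
  expect_equal(sum(plant_water_demand(B, 5.5, cfg0)),
               uptake_field(5.5, sum(B), cfg0), tolerance = 1e-12)
})

test_that("the coupled integrator matches the split-step path on one parcel", {
  ## one plant, no reproduction or death: the continuous block in
  ## isolation.  Operator splitting at the event step is a controlled
  ## approximation of the co-integrated system; over a month of strong
  ## growth the two stay within a few percent, and the gap shrinks as the
  ## event step does.
  sc <- small_scenario(T_end = 30, nx = 8, s = 0,
                       age_mortality_enabled = FALSE, d_b = 1e-6)
  pop0 <- new_population(id = 1L, x = 10, y = 10, age = 50, B = 2)
  co <- run_simulation(sc$cfg, pop0, seed = 1)
  cfg_split <- sc$cfg; cfg_split$coupling <- "split"
  sp <- run_simulation(cfg_split, pop0, seed = 1)
  expect_equal(co$pop$B, sp$pop$B, tolerance = 0.05)
  expect_lt(max(abs(co$grid$W - sp$grid$W)) / max(sp$grid$W), 0.05)
  ## halving the event step roughly halves the splitting gap
  cfg_co2 <- sc$cfg; cfg_co2$dt_event <- 0.1
  cfg_sp2 <- cfg_split; cfg_sp2$dt_event <- 0.1
  co2 <- run_simulation(cfg_co2, pop0, seed = 1)
  sp2 <- run_simulation(cfg_sp2, pop0, seed = 1)
  gap1 <- abs(co$pop$B - sp$pop$B)
  gap2 <- abs(co2$pop$B - sp2$pop$B)
  expect_lt(gap2, gap1)
})
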