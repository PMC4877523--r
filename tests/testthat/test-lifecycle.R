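cfg0 <- sim_config()

test_that("dispersal kernel has the requested mean and median", {
  k <- dispersal_kernel(10, 1.5)
  expect_equal(k$meanlog, log(10) - 1.5^2 / 2)
  set.seed(31)
  d <- rlnorm(1e5, k$meanlog, k$sdlog)
  expect_gt(mean(d), 9.5)
  expect_lt(mean(d), 10.5)
  ## median = mu * exp(-sigma^2/2) ~ 3.25 m: strongly leptokurtic
  expect_equal(median(d), 10 * exp(-1.5^2 / 2), tolerance = 0.03)
  ## degenerate kernel: all distances -> mu
  k0 <- dispersal_kernel(10, 1e-9)
  expect_equal(rlnorm(5, k0$meanlog, k0$sdlog), rep(10, 5), tolerance = 1e-6)
})

test_that("seed positions are isotropic and lost outside the plot", {
  set.seed(7)
  k <- dispersal_kernel(10, 1.5)
  s <- sample_dispersal(c(50, 50), k, c(100, 100), n = 2e4)
  expect_equal(nrow(s), 2e4)
  ## isotropy: mean displacement ~ 0
  expect_lt(abs(mean(s$x - 50)), 0.3)
  expect_lt(abs(mean(s$y - 50)), 0.3)
  ## corner origin with huge kernel: almost everything is lost
  s2 <- sample_dispersal(c(0.01, 0.01), dispersal_kernel(1e4, 1.5),
                         c(100, 100), n = 2000)
  expect_gt(mean(s2$lost), 0.95)
})

test_that("expected seed counts follow the maturity-compensated rate", {
  expect_equal(expected_seeds(0, cfg0), 0)
  ## B = 100 g, s = 0.002, m = 0 (f = 1), dt = 0.2 -> 0.04
  expect_equal(expected_seeds(100, cfg0), 0.04)
  ## m = l: the factor l/m = 1 gives the same rate
  cfg_m <- sim_config(m = 365)
  expect_equal(expected_seeds(100, cfg_m), 0.04)
  ## m = l/2 doubles the per-step rate
  expect_equal(expected_seeds(100, sim_config(m = 182.5)), 0.08)
})

test_that("realized seed counts match their expectation", {
  set.seed(19)
  ## E > 1: floor plus Bernoulli remainder
  E <- rep(2.3, 4e4)
  n <- hybridveg:::sample_seed_counts(E)
  expect_true(all(n %in% c(2L, 3L)))
  expect_lt(abs(mean(n) - 2.3), 3 * sd(n) / sqrt(4e4))
  ## E < 1: plain Bernoulli
  n2 <- hybridveg:::sample_seed_counts(rep(0.04, 4e4))
  expect_true(all(n2 %in% c(0L, 1L)))
  expect_lt(abs(mean(n2) - 0.04), 3 * sqrt(0.04 * 0.96 / 4e4))
})

test_that("establishment honours the density cap", {
  cfg <- sim_config(nx = 10, ny = 10)
  grid <- bare_soil_grid(cfg)
  ## empty parcel: seedling roots at 1 g, age 0
  sdl <- try_establish(c(5, 5), new_population(), grid, cfg)
  expect_equal(sdl$B, 1)
  expect_equal(sdl$age, 0)
  ## 500 g on one 16 m2 parcel = 31.25 g/m2 > K_a = 30: rejected
  big <- new_population(id = 1L, x = 5, y = 5, age = 100, B = 500)
  expect_null(try_establish(c(6, 6), big, grid, cfg))
  ## 470 g = 29.4 g/m2: allowed
  ok <- new_population(id = 1L, x = 5, y = 5, age = 100, B = 470)
  expect_false(is.null(try_establish(c(6, 6), ok, grid, cfg)))
})

test_that("preemptive seedling removal is off by default", {
  cfg <- sim_config(nx = 10, ny = 10)
  dry <- structure(list(O = matrix(10, 10, 10), W = matrix(0.5, 10, 10),
                        dx = 4), class = "soil_grid")
  ## growth rate at 0.5 mm soil water is negative, yet the seedling roots
  expect_lt(growth_rate(1, 0.5, cfg), 0)
  expect_false(is.null(try_establish(c(5, 5), new_population(), dry, cfg)))
  cfg_pre <- sim_config(nx = 10, ny = 10, preemptive_seedling_removal = TRUE)
  expect_null(try_establish(c(5, 5), new_population(), dry, cfg_pre))
})

test_that("death probability matches the threshold formula", {
  ## at the threshold exactly: no stress death
  expect_equal(death_probability(0.8, 1, cfg0), 0)
  expect_equal(death_probability(1, 1, cfg0), 0)
  ## B -> 0: certain death
  expect_equal(death_probability(1e-12, 1, cfg0), 1, tolerance = 1e-9)
  ## B/Bmax = 0.4 with d_b = 0.8: p = 1 - 0.5 = 0.5 per day
  expect_equal(death_probability(0.4, 1, cfg0), 0.5)
  ## step conversion keeps probabilities consistent across step sizes
  expect_equal(death_probability(0.4, 1, cfg0, dt_event = 0.2),
               1 - (1 - 0.5)^0.2)
})

test_that("plants at or above the stress threshold never die of stress", {
  cfg <- sim_config(age_mortality_enabled = FALSE)
  set.seed(23)
  pop <- new_population(id = 1:5000, x = runif(5000, 0, 100),
                        y = runif(5000, 0, 100), age = rep(10, 5000),
                        B = runif(5000, 0.8, 1), Bmax = rep(1, 5000))
  out <- death_step(pop, cfg, dt_event = 1)
  expect_equal(nrow(out), 5000L)
})

test_that("stress mortality realizes the formula probability", {
  cfg <- sim_config(age_mortality_enabled = FALSE)
  set.seed(29)
  n <- 2e4
  pop <- new_population(id = seq_len(n), x = rep(1, n), y = rep(1, n),
                        age = rep(10, n), B = rep(0.4, n), Bmax = rep(1, n))
  out <- death_step(pop, cfg, dt_event = 1)
  surv <- nrow(out) / n
  expect_lt(abs(surv - 0.5), 3 * sqrt(0.25 / n))
})

test_that("age hazard alone yields a mean lifetime of l", {
  cfg <- sim_config(l = 50)  # shorter lifetime keeps the loop small
  set.seed(41)
  n <- 1e4
  alive <- rep(TRUE, n)
  death_day <- rep(NA_real_, n)
  p_day <- 1 - (1 - 1 / 50)^1
  for (day in 1:2000) {
    die <- alive & (runif(n) < p_day)
    death_day[die] <- day
    alive <- alive & !die
    if (!any(alive)) break
  }
  ## geometric lifetime with daily hazard 1/l has mean l
  expect_equal(mean(death_day, na.rm = TRUE), 50,
               tolerance = 3 * 50 / sqrt(n))
  ## and the package's step conversion reproduces the daily hazard
  expect_equal(1 - (1 - 1 / cfg$l)^cfg$dt_event,
               1 - (1 - p_day)^cfg$dt_event)
})

test_that("a lifecycle step produces the expected number of seedlings", {
  cfg <- sim_config(nx = 20, ny = 20, age_mortality_enabled = FALSE,
                    mu_disp = 5)
  grid <- bare_soil_grid(cfg)
  set.seed(13)
  n <- 200
  pop <- new_population(id = seq_len(n), x = runif(n, 20, 60),
                        y = runif(n, 20, 60), age = rep(100, n),
                        B = rep(100, n), Bmax = rep(100, n))
  ## E[seeds] per step = sum B*s*dt = 200*100*0.002*0.2 = 8; a fraction
  ## lands outside the 80 m plot
  reps <- 300
  births <- lost <- blocked <- numeric(reps)
  for (r in seq_len(reps)) {
    lc <- lifecycle_step(pop, grid, cfg, next_id = 1000L)
    births[r] <- lc$events[["births"]]
    lost[r] <- lc$events[["seeds_lost"]]
    blocked[r] <- lc$events[["blocked"]]
  }
  total <- births + lost + blocked
  expect_lt(abs(mean(total) - 8), 3 * sd(total) / sqrt(reps))
  expect_true(all(births <= total))  # establishment never exceeds dispersal
})

test_that("extinction is absorbing and determinism holds", {
  cfg <- sim_config(nx = 10, ny = 10)
  grid <- bare_soil_grid(cfg)
  lc <- lifecycle_step(new_population(), grid, cfg, next_id = 1L)
  expect_equal(nrow(lc$pop), 0L)
  expect_equal(unname(lc$events["births"]), 0L)
  ## pre-maturity plants produce nothing
  cfg_m <- sim_config(nx = 10, ny = 10, m = 200,
                      age_mortality_enabled = FALSE)
  young <- new_population(id = 1:50, x = runif(50, 0, 40),
                          y = runif(50, 0, 40), age = rep(10, 50),
                          B = rep(200, 50), Bmax = rep(200, 50))
  set.seed(1)
  lc2 <- lifecycle_step(young, grid, cfg_m, next_id = 100L)
  expect_equal(unname(lc2$events[["births"]]), 0L)
  ## same seed, same outcome
  set.seed(77)
  a <- lifecycle_step(young, grid, cfg, next_id = 100L)
  set.seed(77)
  b <- lifecycle_step(young, grid, cfg, next_id = 100L)
  expect_identical(a$pop, b$pop)
})
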