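cfg0 <- sim_config(nx = 10, ny = 10)  # 40 x 40 m plot

test_that("quadrat counts tile the plot exhaustively", {
  expect_equal(sum(quadrat_counts(new_population(), 4, cfg0)$counts), 0L)
  pop <- new_population(id = 1:4, x = c(5, 25, 5, 25), y = c(5, 5, 25, 25),
                        age = rep(1, 4), B = rep(1, 4))
  qc <- quadrat_counts(pop, 20, cfg0)
  expect_equal(qc$counts, rep(1L, 4))
  ## total is invariant to the tiling
  set.seed(4)
  pop2 <- new_population(id = 1:57, x = runif(57, 0, 40),
                         y = runif(57, 0, 40), age = rep(1, 57),
                         B = rep(1, 57))
  for (q in c(2, 4, 8, 10, 20))
    expect_equal(sum(quadrat_counts(pop2, q, cfg0)$counts), 57L)
  expect_error(quadrat_counts(pop2, 7, cfg0), "divide")
})

test_that("dispersion indices match hand-computed fixtures", {
  ## uniform counts: variance 0
  expect_equal(index_of_patchiness(c(4, 4, 4, 4)), 1 - 1 / 4)
  expect_equal(index_of_cluster_size(c(4, 4, 4, 4)), -1)
  ## alternating counts [8,0,8,0]: mean 4, sample variance 64/3
  expect_equal(index_of_patchiness(c(8, 0, 8, 0)),
               1 + (64 / 3 - 4) / 16)
  expect_equal(index_of_cluster_size(c(8, 0, 8, 0)), (64 / 3) / 4 - 1)
  expect_error(index_of_patchiness(c(0, 0, 0)), "undefined")
  expect_error(index_of_cluster_size(c(0, 0)), "undefined")
})

test_that("both indices sit at their Poisson null for random patterns", {
  set.seed(101)
  counts <- rpois(1e4, 5)
  expect_equal(index_of_patchiness(counts), 1, tolerance = 0.05)
  expect_equal(index_of_cluster_size(counts), 0, tolerance = 0.05)
})

test_that("the two indices are algebraically consistent", {
  set.seed(55)
  for (i in 1:5) {
    counts <- rnbinom(500, mu = 4, size = 0.8)
    if (mean(counts) == 0) next
    ip <- index_of_patchiness(counts)
    ics <- index_of_cluster_size(counts)
    ## ICS = (IP - 1) * mean  (both derive from the same s^2 and mean)
    expect_equal(ics, (ip - 1) * mean(counts), tolerance = 1e-12)
  }
})

test_that("indices are invariant under periodic translation of positions", {
  cfg <- sim_config(nx = 10, ny = 10)
  set.seed(9)
  pop <- new_population(id = 1:300, x = runif(300, 0, 40)^1,
                        y = 40 * rbeta(300, 2, 5), age = rep(1, 300),
                        B = rep(1, 300))
  shift <- function(v, by, L) (v + by) %% L
  pop2 <- pop
  pop2$x <- shift(pop$x, 8, 40)   # two quadrats along x
  pop2$y <- shift(pop$y, 16, 40)
  q1 <- quadrat_counts(pop, 4, cfg)$counts
  q2 <- quadrat_counts(pop2, 4, cfg)$counts
  expect_equal(sort(q1), sort(q2))
  expect_equal(index_of_patchiness(q1), index_of_patchiness(q2))
  expect_equal(index_of_cluster_size(q1), index_of_cluster_size(q2))
})

test_that("structure summaries report means, modes and normalized histograms", {
  pop <- new_population(id = 1L, x = 1, y = 1, age = 10, B = 5)
  ss <- structure_summaries(pop, cfg0)
  expect_equal(ss$mean_age, 10)
  expect_equal(ss$mean_biomass, 5)
  expect_equal(ss$seedling_fraction, 1)
  expect_equal(ss$plant_density, 1 / 1600)
  set.seed(6)
  pop2 <- new_population(id = 1:400, x = runif(400, 0, 40),
                         y = runif(400, 0, 40),
                         age = stats::rexp(400, 1 / 100),
                         B = c(rep(1.2, 200), stats::rnorm(200, 60, 5)))
  ss2 <- structure_summaries(pop2, cfg0)
  expect_equal(sum(ss2$age_hist$freq), 1, tolerance = 1e-12)
  expect_equal(sum(ss2$biomass_hist$freq), 1, tolerance = 1e-12)
  ## a seedling mode near 1 g and an adult mode near 60 g
  bh <- ss2$biomass_hist
  expect_equal(bh$mid[which.max(bh$freq)], 1.5)
  adult <- bh[bh$mid > 30, ]
  expect_gt(max(adult$freq), 0)
  expect_equal(adult$mid[which.max(adult$freq)], 60.5, tolerance = 3)
  ## empty population is flagged, not an error
  ss0 <- structure_summaries(new_population(), cfg0)
  expect_true(ss0$empty)
  expect_equal(ss0$n_plants, 0L)
})

test_that("mortality by class equals direct id-set arithmetic", {
  pre <- new_population(id = 1:6, x = 1:6, y = 1:6,
                        age = c(2, 5, 40, 40, 400, 400),
                        B = c(0.5, 0.9, 6, 8, 20, 25))
  ## survivors: ids 3 and 5
  post <- pre[pre$id %in% c(3, 5), ]
  mc <- mortality_by_class(pre, post, age_breaks = c(0, 7, 45, Inf),
                           biomass_breaks = c(0, 1, 15, Inf))
  expect_equal(mc$by_age$mortality, c(1, 1 / 2, 1 / 2))
  expect_equal(mc$by_biomass$mortality, c(1, 1 / 2, 1 / 2))
  ## no deaths / all deaths
  expect_equal(mortality_by_class(pre, pre)$by_age$dead, rep(0L, 9))
  all_dead <- mortality_by_class(pre, new_population(),
                                 biomass_breaks = c(0, 1, Inf))
  expect_equal(all_dead$by_biomass$mortality, c(1, 1))
  ## empty classes are NA, not zero
  expect_true(is.na(mc$by_biomass$mortality[
    mc$by_biomass$n == 0][1]) || all(mc$by_biomass$n > 0))
})

test_that("occupancy autocorrelation flags periodic banding", {
  ## synthetic striped occupancy with period 8 parcels
  occ <- outer(1:40, 1:40, function(i, j) ((i + j) %% 8) < 3)
  ac <- occupancy_autocorrelation(occ, lags = c(1, 4, 8))
  expect_gt(ac$correlation[ac$lag == 1], 0.3)
  expect_lt(ac$correlation[ac$lag == 4], 0)
  expect_gt(ac$correlation[ac$lag == 8], 0.8)
  ## spatially random occupancy decorrelates immediately
  set.seed(2)
  occ2 <- matrix(runif(1600) < 0.4, 40, 40)
  ac2 <- occupancy_autocorrelation(occ2, lags = 1:3)
  expect_true(all(abs(ac2$correlation) < 0.1))
})
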