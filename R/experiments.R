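## Experiment presets and replicate orchestration.
##
## Full-scale designs (scale = 1):
##   exp1a  pattern formation: 400 x 400 m (100 x 100 parcels), 1000 plants,
##          aggregated (1% of parcels) or random IC, 5-year runs across a
##          precipitation range, s = 0.002, B_init = 1 g, m = 0.
##   demographic variant: 200 x 200 m, 250 plants in 25 patches, 5 years,
##          s = 0.001.
##   exp1b  trait sweep on the demographic design: mean dispersal distance
##          1-100 m or reproductive maturity 0-240 d, s = 0.001.
##   exp2a  precipitation shift: 200 x 200 m, 250 plants aggregated,
##          1.3 mm/d for 1500 d then 0.8 mm/d, age mortality off after the
##          shift.
##   exp2b  seasonal rainfall: 200 x 200 m, 250 plants in 25 patches,
##          R(t) = 1.3 + A sin(2 pi t / 365), 12-year runs.
##
## `scale` shrinks the linear plot side; plant and patch numbers shrink
## with the area (scale^2) so densities are preserved.

scale_len <- function(n, scale) max(2L, as.integer(round(n * scale)))
scale_n <- function(n, scale) max(1L, as.integer(round(n * scale^2)))

demographic_cfg <- function(R, scale = 1, s = 0.001, T_years = 5,
                            seed = NULL, ...) {
  sim_config(nx = scale_len(50, scale), ny = scale_len(50, scale),
             rain = rainfall_regime("constant", R0 = R),
             s = s, T_end = round(T_years * 365), seed = seed,
             summary_every = 5, snapshot_every = Inf, dt_int = 0.1, ...)
}

run_one <- function(cfg, n_plants, n_patches, ic = "aggregated", seed) {
  set.seed(seed)
  pop0 <- init_population(cfg, ic, n_plants,
                          n_patches = if (ic == "aggregated") n_patches)
  run_simulation(cfg, pop0, seed = NULL)
}

#' Precipitation sweep (pattern formation experiment)
#'
#' Runs the pattern-formation design across a range of constant rainfall
#' values and one or both initial spatial conditions, reporting final
#' biomass density and the fraction of occupied parcels, plus the final
#' occupancy matrices for pattern diagnostics.  At `scale = 0` no
#' simulation is run; the configurations are returned for inspection.
#'
#' @param R_values Constant rainfall levels (mm d\eqn{^{-1}}).
#' @param ic Initial condition(s): `"aggregated"`, `"random"` or both.
#' @param scale Linear desk-scale factor in (0, 1]; 1 is the full
#'   400 x 400 m design with 1000 plants.
#' @param reps Replicates per configuration.
#' @param seed Base RNG seed; each run gets a distinct derived seed.
#' @param T_years Run length (years).
#' @return A list with `table` (one row per run: `R`, `ic`, `rep`,
#'   `n_plants`, `biomass_density`, `occupied_fraction`) and `occupancy`
#'   (list of logical matrices, one per row).  At `scale = 0`, a list of
#'   configs.
#' @export
exp1a_precip_sweep <- function(R_values = c(0.6, 0.9, 1.3, 1.7),
                               ic = "aggregated", scale = 1, reps = 1,
                               seed = 1, T_years = 5) {
  stopifnot(scale >= 0, scale <= 1)
  make_cfg <- function(R, sc, seed = NULL)
    sim_config(nx = scale_len(100, sc), ny = scale_len(100, sc),
               rain = rainfall_regime("constant", R0 = R),
               s = 0.002, B_init_range = c(1, 1), m = 0,
               T_end = round(T_years * 365), seed = seed,
               summary_every = 5, snapshot_every = Inf, dt_int = 0.1)
  if (scale == 0)  # config echo of the full-scale design, nothing run
    return(lapply(stats::setNames(R_values, paste0("R", R_values)),
                  make_cfg, sc = 1))
  n_plants <- scale_n(1000, scale)
  grid <- expand.grid(R = R_values, ic = ic, rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  occupancy <- vector("list", nrow(grid))
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- make_cfg(grid$R[i], sc = scale)
    out <- run_one(cfg, n_plants, n_patches = NULL, ic = grid$ic[i],
                   seed = seed + 1000L * i)
    occ <- parcel_biomass(out$pop, cfg) > 0
    occupancy[[i]] <- occ
    last <- nrow(out$series)
    res[[i]] <- data.frame(
      R = grid$R[i], ic = grid$ic[i], rep = grid$rep[i],
      n_plants = out$series$n_plants[last],
      biomass_density = out$series$biomass_density[last],
      occupied_fraction = mean(occ))
  }
  list(table = do.call(rbind, res), occupancy = occupancy)
}

#' Demographic rainfall experiment
#'
#' Replicated runs of the demographic design (200 x 200 m, 250 plants in
#' 25 patches, 5 years, `s = 0.001`) across rainfall levels, summarizing
#' the final population: biomass density, mean individual biomass,
#' seedling fraction and plant density.
#'
#' @param R_values Constant rainfall levels (mm d\eqn{^{-1}}).
#' @param reps Replicates per level.
#' @param scale Linear desk-scale factor in (0, 1].
#' @param seed Base RNG seed.
#' @return A list with `runs` (one row per run) and `summary` (replicate
#'   means per rainfall level).
#' @export
exp1_demography <- function(R_values = c(0.9, 1.3, 1.5, 1.7), reps = 5,
                            scale = 1, seed = 1) {
  n_plants <- scale_n(250, scale)
  n_patches <- scale_n(25, scale)
  rows <- list()
  for (i in seq_along(R_values)) {
    for (k in seq_len(reps)) {
      cfg <- demographic_cfg(R_values[i], scale)
      out <- run_one(cfg, n_plants, n_patches, "aggregated",
                     seed = seed + 1000L * i + k)
      ss <- structure_summaries(out$pop, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        R = R_values[i], rep = k, n_plants = ss$n_plants,
        biomass_density = sum(out$pop$B) / (cfg$nx * cfg$ny * cfg$dx^2),
        mean_biomass = ss$mean_biomass,
        seedling_fraction = ss$seedling_fraction,
        plant_density = ss$plant_density)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- stats::aggregate(
    runs[c("n_plants", "biomass_density", "mean_biomass",
           "seedling_fraction", "plant_density")],
    by = list(R = runs$R), FUN = mean, na.rm = TRUE)
  list(runs = runs, summary = agg)
}

#' Plant-trait sweep (dispersal distance / reproductive maturity)
#'
#' Replicated 5-year runs of the demographic design at a fixed rainfall of
#' 1.3 mm d\eqn{^{-1}}, varying either the mean dispersal distance or the
#' reproductive maturity, and measuring the spatial dispersion of the
#' final population (Lloyd IP and David-Moore ICS on quadrat counts).
#'
#' @param param `"mu_disp"` (m) or `"m"` (d).
#' @param values Parameter values to sweep.
#' @param reps Replicates per value.
#' @param scale Linear desk-scale factor in (0, 1].
#' @param seed Base RNG seed.
#' @param quadrat_size Quadrat side for the indices (m).
#' @return A list with `runs` (value, rep, IP, ICS, n_plants) and
#'   `summary` (means and sds per value).  Runs whose population went
#'   extinct report `NA` indices.
#' @export
exp1b_trait_sweep <- function(param = c("mu_disp", "m"),
                              values = if (param == "mu_disp")
                                c(1, 5, 20, 80) else c(0, 60, 120, 240),
                              reps = 5, scale = 1, seed = 1,
                              quadrat_size = 4) {
  param <- match.arg(param)
  n_plants <- scale_n(250, scale)
  n_patches <- scale_n(25, scale)
  rows <- list()
  for (i in seq_along(values)) {
    for (k in seq_len(reps)) {
      args <- list(R = 1.3, scale = scale)
      args[[param]] <- values[i]
      cfg <- do.call(demographic_cfg, args)
      out <- run_one(cfg, n_plants, n_patches, "aggregated",
                     seed = seed + 1000L * i + k)
      qc <- if (nrow(out$pop))
        quadrat_counts(out$pop, quadrat_size, cfg) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        value = values[i], rep = k, n_plants = nrow(out$pop),
        IP = if (!is.null(qc) && mean(qc$counts) > 0)
          index_of_patchiness(qc) else NA_real_,
        ICS = if (!is.null(qc) && mean(qc$counts) > 0)
          index_of_cluster_size(qc) else NA_real_)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- stats::aggregate(runs[c("IP", "ICS", "n_plants")],
                          by = list(value = runs$value),
                          FUN = mean, na.rm = TRUE)
  sds <- stats::aggregate(runs[c("IP", "ICS")],
                          by = list(value = runs$value),
                          FUN = stats::sd, na.rm = TRUE)
  names(sds)[-1] <- paste0(names(sds)[-1], "_sd")
  list(runs = runs, summary = merge(agg, sds, by = "value"))
}

#' Precipitation shift experiment
#'
#' Grows a population (250 plants, aggregated IC, 200 x 200 m) under
#' constant `R0` for `t_shift` days, then drops rainfall to `R1` with age
#' mortality disabled, and assesses the population `assess_after` days
#' later.  Reports pre- and post-shift spatial dispersion (IP, ICS),
#' survival, and mortality fractions by pre-shift age and biomass class.
#'
#' @param reps Replicates.
#' @param scale Linear desk-scale factor in (0, 1].
#' @param seed Base RNG seed.
#' @param R0,R1 Pre- and post-shift rainfall (mm d\eqn{^{-1}}).
#' @param t_shift Shift time (d).
#' @param assess_after Assessment delay after the shift (d).
#' @param quadrat_size Quadrat side for the indices (m).
#' @param shift Set `FALSE` to run the no-shift control (rainfall stays at
#'   `R0`; age mortality still disabled after `t_shift` so the control is
#'   comparable).
#' @return A list with `runs` (per replicate: IP/ICS pre and post, plant
#'   counts, survival flag), `mortality_by_biomass` and `mortality_by_age`
#'   (replicate-averaged class mortality fractions) and `summary`
#'   (replicate means of the run columns).
#' @export
exp2a_shift <- function(reps = 5, scale = 1, seed = 1, R0 = 1.3, R1 = 0.8,
                        t_shift = 1500, assess_after = 365,
                        quadrat_size = 4, shift = TRUE) {
  n_plants <- scale_n(250, scale)
  n_patches <- scale_n(25, scale)
  rows <- list(); mort_b <- list(); mort_a <- list()
  for (k in seq_len(reps)) {
    cfg1 <- sim_config(nx = scale_len(50, scale), ny = scale_len(50, scale),
                       rain = rainfall_regime("constant", R0 = R0),
                       T_end = t_shift, summary_every = 5,
                       snapshot_every = Inf, dt_int = 0.1)
    out1 <- run_one(cfg1, n_plants, n_patches, "aggregated",
                    seed = seed + k)
    pre <- out1$pop
    cfg2 <- sim_config(nx = cfg1$nx, ny = cfg1$ny,
                       rain = rainfall_regime("constant",
                                              R0 = if (shift) R1 else R0),
                       T_end = t_shift + assess_after,
                       age_mortality_enabled = FALSE,
                       summary_every = 5, snapshot_every = Inf,
                       dt_int = 0.1)
    out2 <- run_simulation(cfg2, pop0 = pre, grid0 = out1$grid,
                           t0 = t_shift, seed = NULL,
                           next_id = out1$next_id)
    post <- out2$pop
    idx <- function(p, f) if (nrow(p) && mean(quadrat_counts(
      p, quadrat_size, cfg1)$counts) > 0)
      f(quadrat_counts(p, quadrat_size, cfg1)) else NA_real_
    rows[[k]] <- data.frame(
      rep = k, n_pre = nrow(pre), n_post = nrow(post),
      IP_pre = idx(pre, index_of_patchiness),
      ICS_pre = idx(pre, index_of_cluster_size),
      IP_post = idx(post, index_of_patchiness),
      ICS_post = idx(post, index_of_cluster_size),
      survived = nrow(post) > 0)
    mc <- mortality_by_class(pre, post)
    mort_b[[k]] <- mc$by_biomass$mortality
    mort_a[[k]] <- mc$by_age$mortality
  }
  runs <- do.call(rbind, rows)
  mc0 <- mortality_by_class(new_population(id = 1, x = 0, y = 0,
                                           age = 0, B = 1),
                            new_population())
  avg <- function(lst, template) {
    m <- do.call(cbind, lst)
    data.frame(class = template$class,
               mortality = rowMeans(m, na.rm = TRUE),
               n_reps = rowSums(!is.na(m)))
  }
  list(runs = runs,
       mortality_by_biomass = avg(mort_b, mc0$by_biomass),
       mortality_by_age = avg(mort_a, mc0$by_age),
       summary = colMeans(runs[setdiff(names(runs), "rep")], na.rm = TRUE))
}

#' Population viability under shifts of varying size and timing
#'
#' Survival probability across replicate runs for combinations of shift
#' amplitude, shift timing and initial condition, with a larger founding
#' population (2000 plants at full scale).
#'
#' @param amplitudes Negative rainfall changes (mm d\eqn{^{-1}}),
#'   subtracted from the 1.3 mm baseline.
#' @param timings Shift times (d).
#' @param ic Initial condition(s).
#' @param reps Replicates per combination.
#' @param scale Linear desk-scale factor in (0, 1].
#' @param seed Base RNG seed.
#' @param T_after Days simulated after the shift before judging survival.
#' @return Data frame with survival probability per combination.
#' @export
exp2a_viability <- function(amplitudes = c(0.5, 0.7, 0.9),
                            timings = c(1, 1500), ic = "aggregated",
                            reps = 40, scale = 1, seed = 1,
                            T_after = 730) {
  n_plants <- scale_n(2000, scale)
  grid <- expand.grid(amplitude = amplitudes, t_shift = timings, ic = ic,
                      stringsAsFactors = FALSE)
  grid$survival <- NA_real_
  for (i in seq_len(nrow(grid))) {
    surv <- logical(reps)
    for (k in seq_len(reps)) {
      sh <- exp2a_shift(reps = 1, scale = scale,
                        seed = seed + 10000L * i + k,
                        R1 = 1.3 - grid$amplitude[i],
                        t_shift = grid$t_shift[i], assess_after = T_after)
      surv[k] <- sh$runs$survived[1]
    }
    grid$survival[i] <- mean(surv)
  }
  grid
}

#' Seasonal rainfall experiment
#'
#' Replicated 12-year runs under sinusoidal rainfall
#' \eqn{R(t) = 1.3 + A \sin(2\pi t/365)} for a set of amplitudes,
#' summarizing the total-biomass series over the last 4 years (mean,
#' maximum, minimum, oscillation amplitude) and the dominant oscillation
#' period from the periodogram of the detrended series.
#'
#' @param amplitudes Seasonal amplitudes A (mm d\eqn{^{-1}}).
#' @param reps Replicates per amplitude.
#' @param scale Linear desk-scale factor in (0, 1].
#' @param seed Base RNG seed.
#' @return A list with `runs` (per run: amplitude, rep, mean/max/min total
#'   biomass over years 8-12, oscillation amplitude, dominant period in
#'   days) and `summary` (means per amplitude).
#' @export
exp2b_seasonal <- function(amplitudes = c(0, 0.3, 0.45, 0.6, 0.9),
                           reps = 3, scale = 1, seed = 1) {
  n_plants <- scale_n(250, scale)
  n_patches <- scale_n(25, scale)
  rows <- list()
  for (i in seq_along(amplitudes)) {
    for (k in seq_len(reps)) {
      cfg <- sim_config(nx = scale_len(50, scale), ny = scale_len(50, scale),
                        rain = rainfall_regime("sinusoid", R0 = 1.3,
                                               amplitude = amplitudes[i]),
                        T_end = 12 * 365, summary_every = 5,
                        snapshot_every = Inf, dt_int = 0.1)
      out <- run_one(cfg, n_plants, n_patches, "aggregated",
                     seed = seed + 1000L * i + k)
      sr <- out$series
      last4 <- sr[sr$time >= 8 * 365, ]
      tb <- last4$total_biomass
      rows[[length(rows) + 1L]] <- data.frame(
        amplitude = amplitudes[i], rep = k,
        mean_biomass = mean(tb), max_biomass = max(tb),
        min_biomass = min(tb), osc_amplitude = max(tb) - min(tb),
        dominant_period = dominant_period(last4$time, tb))
    }
  }
  runs <- do.call(rbind, rows)
  agg <- stats::aggregate(
    runs[c("mean_biomass", "max_biomass", "min_biomass", "osc_amplitude",
           "dominant_period")],
    by = list(amplitude = runs$amplitude), FUN = mean, na.rm = TRUE)
  list(runs = runs, summary = agg)
}

## Dominant period (d) of a regularly sampled series via the raw
## periodogram of the demeaned series; NA for flat series.
dominant_period <- function(time, x) {
  if (length(x) < 8 || stats::sd(x) == 0) return(NA_real_)
  dt <- diff(time[1:2])
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  freq <- (1:(n %/% 2 - 1)) / (n * dt)
  1 / freq[which.max(p)]
}

#' Ring-formation scenario preset
#'
#' Qualitative high-resolution scenario in which a single small patch under
#' moderate seasonal rainfall can develop into an expanding ring: 50 x 50 m
#' plot at 1 m parcels, short mean dispersal (5 m), rainfall oscillating
#' between 1.0 and 1.6 mm d\eqn{^{-1}} over the year, one 10-plant patch.
#'
#' @return A list with `cfg` (the [sim_config()]) and the initial
#'   condition fields `n_plants` and `n_patches`.
#' @export
ring_preset <- function() {
  list(cfg = sim_config(nx = 50, ny = 50, dx = 1, mu_disp = 5,
                        rain = rainfall_regime("sinusoid", R0 = 1.3,
                                               amplitude = 0.3),
                        T_end = 4 * 365, summary_every = 5,
                        snapshot_every = 30, dt_int = 0.1),
       n_plants = 10, n_patches = 1)
}
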