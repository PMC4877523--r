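#' Run the hybrid simulation
#'
#' Orchestrates the hybrid time loop.  Each event step of length
#' `cfg$dt_event` does, in order: (1) the continuous block — plant biomass
#' ODEs and parcel water ODEs advanced together over the step (by shared
#' RK4 sub-steps of `cfg$dt_int` under the default `"cointegrated"`
#' coupling, with the per-parcel biomass density refreshed at every stage;
#' or sequentially under `"split"`); (2) the discrete lifecycle events —
#' seed dispersal and establishment, stochastic death, aging; (3)
#' bookkeeping of the output series.  Runs are reproducible: a given
#' `seed` yields bit-identical output.
#'
#' The cointegrated path executes in compiled code (drawing from R's RNG);
#' the split path runs through [metabolism_step()], [water_step()] and
#' [lifecycle_step()] in R and is mainly useful for numerical comparisons.
#'
#' @param cfg A [sim_config()].
#' @param pop0 Initial population (default: empty plot).
#' @param grid0 Initial soil grid (default: [bare_soil_grid()]).
#' @param t0 Start time (d); the run covers `[t0, cfg$T_end]`.
#' @param seed RNG seed for this run (default `cfg$seed`; `NULL` leaves the
#'   RNG state alone, e.g. when continuing a run).
#' @param next_id First unused plant id (for continuation runs).
#' @return An object of class `sim_output`: list with `series` (data frame
#'   of `time`, `n_plants`, `total_biomass`, `mean_age`, `mean_biomass`,
#'   `biomass_density`, `seedling_fraction`), `snapshots` (list of
#'   `list(time, plants, O, W)`), `events` (cumulative counts), `pop`,
#'   `grid`, `next_id`, `t_end` (final state, usable to continue the run),
#'   `n_clamps` and the config echo `cfg`.
#' @export
#' @examples
#' cfg <- sim_config(nx = 10, ny = 10, T_end = 5, seed = 1,
#'                   rain = rainfall_regime("constant", R0 = 1.0))
#' pop <- init_population(cfg, "random", 20)
#' out <- run_simulation(cfg, pop)
#' tail(out$series, 2)
run_simulation <- function(cfg, pop0 = NULL, grid0 = NULL, t0 = 0,
                           seed = cfg$seed, next_id = NULL) {
  validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid0)) grid0 <- bare_soil_grid(cfg)
  if (is.null(pop0)) pop0 <- new_population()
  stopifnot(inherits(grid0, "soil_grid"),
            all(dim(grid0$O) == c(cfg$nx, cfg$ny)))
  if (is.null(next_id))
    next_id <- if (nrow(pop0)) max(pop0$id) + 1L else 1L

  v <- list(id = as.integer(pop0$id), x = as.numeric(pop0$x),
            y = as.numeric(pop0$y), age = as.numeric(pop0$age),
            B = as.numeric(pop0$B), Bmax = as.numeric(pop0$Bmax))
  grid <- grid0
  n_steps <- max(0L, as.integer(round((cfg$T_end - t0) / cfg$dt_event)))
  rec_every <- max(1L, as.integer(round(cfg$summary_every / cfg$dt_event)))
  snap_every <- if (is.finite(cfg$snapshot_every))
    max(1L, as.integer(round(cfg$snapshot_every / cfg$dt_event))) else NA_integer_

  area <- cfg$nx * cfg$ny * cfg$dx^2
  as_pop <- function() new_population(id = v$id, x = v$x, y = v$y,
                                      age = v$age, B = v$B, Bmax = v$Bmax)
  snapshots <- list()
  take_snapshot <- function(t) {
    snapshots[[length(snapshots) + 1L]] <<-
      list(time = t, plants = as_pop(), O = grid$O, W = grid$W)
  }
  row0 <- c(t0, length(v$B), sum(v$B), sum(v$age), sum(v$age < 30), 0)
  events <- c(births = 0, deaths_stress = 0, deaths_age = 0,
              seeds_lost = 0, blocked = 0)
  n_clamps <- 0
  if (!is.na(snap_every)) take_snapshot(t0)

  rows <- list(matrix(row0, 1))
  if (cfg$coupling == "cointegrated") {
    par_cpp <- cfg[c("nx", "ny", "dx", "alpha", "k2", "W0", "r_w", "D_O",
                     "D_W", "g_max", "k1", "b", "Kp", "d", "boundary",
                     "infiltration_denominator", "dt_event", "dt_int",
                     "s", "l", "m", "mu_disp", "sigma_disp", "K_a", "d_b",
                     "age_mortality_enabled", "age_mortality_mode",
                     "preemptive_seedling_removal")]
    par_cpp$rain_mode <- match(cfg$rain$mode,
                               c("constant", "shift", "sinusoid")) - 1L
    par_cpp$rain_R0 <- cfg$rain$R0
    par_cpp$rain_R1 <- cfg$rain$R1
    par_cpp$rain_t_shift <- cfg$rain$t_shift
    par_cpp$rain_amplitude <- cfg$rain$amplitude
    par_cpp$rain_period <- cfg$rain$period
    snap_steps <- if (!is.na(snap_every) && n_steps >= snap_every)
      seq.int(snap_every, n_steps, by = snap_every) else integer()
    bounds <- unique(c(snap_steps, n_steps))
    bounds <- bounds[bounds > 0]
    done <- 0L
    for (b in bounds) {
      res <- .run_hybrid(grid$O, grid$W, v, par_cpp,
                         t0 + done * cfg$dt_event, b - done, next_id,
                         rec_every, done)
      grid$O <- res$O
      grid$W <- res$W
      v <- res$pop
      next_id <- res$next_id
      events <- events + res$events
      n_clamps <- n_clamps + res$n_clamps
      if (res$k_rec > 0)
        rows[[length(rows) + 1L]] <-
          res$series[seq_len(res$k_rec), , drop = FALSE]
      done <- b
      if (b %in% snap_steps) take_snapshot(t0 + b * cfg$dt_event)
    }
  } else {
    for (step in seq_len(n_steps)) {
      t <- t0 + (step - 1L) * cfg$dt_event
      pop_df <- metabolism_step(as_pop(), grid, cfg)
      grid <- water_step(grid, parcel_biomass(pop_df, cfg), cfg,
                         dt = cfg$dt_event, t0 = t)
      v <- list(id = pop_df$id, x = pop_df$x, y = pop_df$y,
                age = pop_df$age, B = pop_df$B, Bmax = pop_df$Bmax)
      lc <- lifecycle_step_vec(v, grid$W, cfg, next_id)
      v <- lc$v
      next_id <- lc$next_id
      events <- events + lc$events
      t_next <- t0 + step * cfg$dt_event
      if (step %% rec_every == 0L)
        rows[[length(rows) + 1L]] <-
          matrix(c(t_next, length(v$B), sum(v$B), sum(v$age),
                   sum(v$age < 30), 0), 1)
      if (!is.na(snap_every) && step %% snap_every == 0L)
        take_snapshot(t_next)
    }
  }

  raw <- do.call(rbind, rows)
  n <- raw[, 2]
  series <- data.frame(
    time = raw[, 1], n_plants = as.integer(n), total_biomass = raw[, 3],
    mean_age = ifelse(n > 0, raw[, 4] / n, NA_real_),
    mean_biomass = ifelse(n > 0, raw[, 3] / n, NA_real_),
    biomass_density = raw[, 3] / area,
    seedling_fraction = ifelse(n > 0, raw[, 5] / n, NA_real_))
  storage.mode(events) <- "integer"
  structure(list(series = series, snapshots = snapshots, events = events,
                 pop = as_pop(), grid = grid, next_id = next_id,
                 t_end = t0 + n_steps * cfg$dt_event,
                 n_clamps = n_clamps, cfg = cfg),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("<sim_output> %g d simulated, %d series records, %d snapshots\n",
              x$t_end, n, length(x$snapshots)))
  cat(sprintf("  final: %d plants, %.4g g total biomass (%.3g g/m2)\n",
              x$series$n_plants[n], x$series$total_biomass[n],
              x$series$biomass_density[n]))
  cat(sprintf("  events: %s\n",
              paste(names(x$events), x$events, sep = "=", collapse = " ")))
  invisible(x)
}
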